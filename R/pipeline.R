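# Pipeline orchestration: structured run configuration, stage execution
# in the analysis order (catalog -> paralogs -> kaks -> tree ->
# expression -> mirna-scan -> hairpin -> degradome), TSV + JSON outputs
# and a reproducibility manifest.

.CONFIG_KEYS <- c("seed", "out_dir", "stages", "thresholds", "simulate")
.THRESHOLD_KEYS <- c("cip", "calp", "evalue", "rpkm", "alpha",
                     "alpha_strict", "expectation", "upe", "min_reads",
                     "bootstrap")
.STAGE_NAMES <- c("catalog", "paralogs", "kaks", "tree", "expression",
                  "mirna_scan", "hairpin", "degradome")

#' Default run configuration
#'
#' Thresholds default to the printed analysis cut-offs: CIP 60%, CALP
#' 70%, BLASTP E-value 1e-40 (recorded; not applied in the
#' global-alignment grouping mode), RPKM 2, significance 0.05 / 0.01,
#' expectation 3.0, target-accessibility UPE 25.0 (recorded; applied only
#' with a thermodynamic folding backend), minimum read support 5 (reads
#' greater than four), 1000 bootstrap replicates.
#'
#' @param seed Integer seed used by every stochastic stage.
#' @return Nested configuration list.
#' @export
defaultRunConfig <- function(seed = 1) {
  list(seed = seed, out_dir = NULL,
       stages = setNames(as.list(rep(TRUE, length(.STAGE_NAMES))),
                         .STAGE_NAMES),
       thresholds = list(cip = 60, calp = 70, evalue = 1e-40, rpkm = 2,
                         alpha = 0.05, alpha_strict = 0.01,
                         expectation = 3.0, upe = 25.0, min_reads = 5,
                         bootstrap = 1000),
       simulate = list(genes_per_group = c(3, 3, 2, 3, 4, 2),
                       ancestor_codons = 570, branch_rate = 0.25,
                       dnds = 0.3, n_targets = 15, srna_depth = 10000,
                       signal_to_background = 10,
                       qpcr_folds = c(CK = 1, MeJA = 4),
                       library_sizes = c(1e6, 1e6)))
}

#' Read a run configuration file
#'
#' YAML with the same structure as [defaultRunConfig()]; unknown keys are
#' rejected, known keys override the defaults.
#'
#' @param path YAML file.
#' @return Configuration list.
#' @export
readRunConfig <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- defaultRunConfig()
  bad <- setdiff(names(user), .CONFIG_KEYS)
  if (length(bad) > 0)
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  if (!is.null(user$thresholds)) {
    bad <- setdiff(names(user$thresholds), .THRESHOLD_KEYS)
    if (length(bad) > 0)
      stop("unknown threshold key(s): ", paste(bad, collapse = ", "))
  }
  if (!is.null(user$stages)) {
    bad <- setdiff(names(user$stages), .STAGE_NAMES)
    if (length(bad) > 0)
      stop("unknown stage key(s): ", paste(bad, collapse = ", "))
  }
  for (k in intersect(names(user), c("seed", "out_dir")))
    cfg[[k]] <- user[[k]]
  for (k in c("stages", "thresholds", "simulate"))
    if (!is.null(user[[k]])) cfg[[k]] <- modifyList(cfg[[k]], user[[k]])
  th <- unlist(cfg$thresholds)
  if (any(th <= 0)) stop("thresholds must be positive")
  cfg
}

.config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

.write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

.stage_log <- function(con, stage, seed, hash, msg) {
  line <- sprintf("[%s] seed=%d config=%s %s", stage, seed, hash, msg)
  writeLines(line, con)
}

#' Run the full synthetic-data analysis pipeline
#'
#' Generates a synthetic gene family, miRNA locus, and expression /
#' small-RNA / degradome libraries from the seeded generators, then
#' executes the analysis stages in order, writing per-stage TSV tables,
#' JSON summaries, a plain-text log and a manifest (config hash, seed,
#' package version) into `outDir`. A failing stage aborts with the stage
#' name in the error. Rerunning with the same configuration reproduces
#' the outputs and manifest hash.
#'
#' @param config Configuration list (see [defaultRunConfig()],
#'   [readRunConfig()]).
#' @param outDir Output directory (created if needed); overrides
#'   `config$out_dir`.
#' @return Invisibly, a list of per-stage summaries (also written as
#'   JSON).
#' @export
runPipeline <- function(config = defaultRunConfig(), outDir = NULL) {
  outDir <- outDir %||% config$out_dir %||% stop("no output directory")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  th <- config$thresholds
  sim <- config$simulate
  seed <- config$seed
  hash <- .config_hash(config[setdiff(names(config), "out_dir")])
  logpath <- file.path(outDir, "run.log")
  logcon <- file(logpath, open = "wt")
  on.exit(close(logcon))
  summaries <- list()
  run_stage <- function(stage, fun) {
    if (!isTRUE(config$stages[[stage]])) return(invisible(NULL))
    .stage_log(logcon, stage, seed, hash, "start")
    res <- tryCatch(fun(), error = function(e)
      stop("stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
    summaries[[stage]] <<- res
    jsonlite::write_json(res, file.path(outDir,
                                        paste0(stage, ".summary.json")),
                         auto_unbox = TRUE, digits = NA)
    .stage_log(logcon, stage, seed, hash, "done")
    res
  }

  fam <- simulateGeneFamily(
    genesPerGroup = sim$genes_per_group,
    ancestorCodons = sim$ancestor_codons,
    branchRate = sim$branch_rate, dnds = sim$dnds, seed = seed)
  writeXStringSet(fam$cds, file.path(outDir, "family_cds.fasta"))
  catalog <- NULL

  run_stage("catalog", function() {
    catalog <<- buildCatalog(fam$cds)
    f <- as.data.frame(geneFeatures(catalog))
    .write_tsv(f, file.path(outDir, "catalog.tsv"))
    list(genes = nrow(f), orf_bp_range = range(f$orf_bp),
         mw_range = range(f$mw, na.rm = TRUE))
  })

  groups <- NULL
  run_stage("paralogs", function() {
    if (is.null(catalog)) catalog <<- buildCatalog(fam$cds)
    pg <- paralogGroups(proteinSeqs(catalog), cipMin = th$cip,
                        calpMin = th$calp)
    groups <<- pg$groups
    tab <- data.frame(
      group = rep(seq_along(pg$groups), lengths(pg$groups)),
      gene_id = unlist(pg$groups))
    .write_tsv(tab, file.path(outDir, "paralog_groups.tsv"))
    .write_tsv(pg$pairs, file.path(outDir, "paralog_pairs.tsv"))
    list(n_groups = length(pg$groups),
         genes_in_groups = sum(lengths(pg$groups)),
         singletons = length(pg$singletons))
  })

  run_stage("kaks", function() {
    if (is.null(groups)) stop("paralog stage required")
    rows <- list()
    for (g in seq_along(groups)) {
      mem <- groups[[g]]
      for (pair in utils::combn(mem, 2, simplify = FALSE)) {
        a <- pair[1]; b <- pair[2]
        aln <- globalAlign(
          setNames(as.character(proteinSeqs(catalog)[a]), a),
          setNames(as.character(proteinSeqs(catalog)[b]), b))
        da <- fam$domains[fam$domains$gene_id == a, ]
        db <- fam$domains[fam$domains$gene_id == b, ]
        kk <- domainKaKs(fam$cds[[a]], fam$cds[[b]], aln, da, db)
        kk$group <- g; kk$id_a <- a; kk$id_b <- b
        rows[[length(rows) + 1]] <- kk
      }
    }
    tab <- do.call(rbind, rows)
    .write_tsv(tab, file.path(outDir, "kaks.tsv"))
    orf <- tab[tab$region == "ORF", ]
    cua <- tab[tab$region == "CuA", ]
    list(pairs = nrow(orf), mean_ka_orf = mean(orf$ka, na.rm = TRUE),
         mean_ks_orf = mean(orf$ks, na.rm = TRUE),
         mean_ratio_orf = mean(orf$ratio, na.rm = TRUE),
         mean_ratio_cua = mean(cua$ratio, na.rm = TRUE))
  })

  run_stage("tree", function() {
    if (is.null(catalog)) catalog <<- buildCatalog(fam$cds)
    prots <- as.character(proteinSeqs(catalog))
    if (length(unique(nchar(prots))) != 1)
      stop("tree stage needs equal-length proteins")
    tr <- bootstrapSupport(prots, nReplicates = th$bootstrap,
                           seed = seed)
    ape::write.tree(tr, file.path(outDir, "nj_tree.nwk"))
    list(taxa = length(prots), bootstrap = th$bootstrap,
         min_support = min(tr$node.label), max_support = 100)
  })

  run_stage("expression", function() {
    cnt <- simulateCounts(nGenes = length(fam$cds),
                          foldChanges = rep(c(1, 4), length.out =
                                            length(fam$cds)),
                          librarySizes = sim$library_sizes, seed = seed)
    r <- rpkm(cnt$counts, cnt$lengths, cnt$totals)
    expressed <- expressedFilter(r, threshold = th$rpkm)
    de <- fisherDE(cnt$counts[expressed, 1], cnt$totals[1],
                   cnt$counts[expressed, 2], cnt$totals[2],
                   alpha = th$alpha)
    de$gene_id <- expressed
    .write_tsv(cbind(gene_id = rownames(r), as.data.frame(r)),
               file.path(outDir, "rpkm.tsv"))
    .write_tsv(de, file.path(outDir, "fisher_de.tsv"))
    qp <- simulateQpcr(folds = sim$qpcr_folds, seed = seed)
    fc <- ddctFoldChange(qp, control = attr(qp, "control"))
    .write_tsv(fc, file.path(outDir, "qpcr_fold_changes.tsv"))
    list(expressed = length(expressed),
         significant = sum(de$significant),
         qpcr_folds = setNames(fc$fold, fc$condition))
  })

  mir <- NULL; sites <- NULL
  run_stage("mirna_scan", function() {
    mir <<- simulateMirLocus(targets = fam$cds,
                             nTargets = min(sim$n_targets,
                                            length(fam$cds)),
                             seed = seed)
    lib <- simulateSrnaLibrary(mir, depth = sim$srna_depth, seed = seed)
    .write_tsv(lib, file.path(outDir, "srna_library.tsv"))
    kept <- filterSrna(lib, minReads = th$min_reads)
    sites <<- targetScan(kept$seq[1], mir$transcripts,
                         maxExpectation = th$expectation)
    .write_tsv(sites, file.path(outDir, "target_sites.tsv"))
    list(library_reads = sum(lib$count), kept_srnas = nrow(kept),
         transcripts_with_sites = length(unique(sites$transcript_id)))
  })

  hairpins <- NULL
  run_stage("hairpin", function() {
    if (is.null(mir)) stop("mirna_scan stage required")
    loci <- genomeMatch(mir$mature, mir$genome)
    verdicts <- list()
    best <- NULL
    for (k in seq_len(nrow(loci))) {
      for (cand in extractAndFold(mir$genome, loci[k, ])) {
        ann <- annotateMirna(cand, mir$mature)
        verdicts[[length(verdicts) + 1]] <- ann
        if (isTRUE(ann@verdict) && is.null(best)) best <- ann
      }
    }
    hairpins <<- verdicts
    if (!is.null(best)) {
      writeLines(c(paste0(">hairpin ", best@seqname, ":", best@start,
                          "-", best@end, "(", best@strand, ")"),
                   best@window_seq, best@structure),
                 file.path(outDir, "hairpin.dotbracket"))
    }
    list(loci = nrow(loci), candidates = length(verdicts),
         passing = sum(vapply(verdicts, function(x) isTRUE(x@verdict),
                              TRUE)))
  })

  run_stage("degradome", function() {
    if (is.null(mir) || is.null(sites)) stop("mirna_scan stage required")
    prof <- simulateDegradome(mir$transcripts, mir$truth,
                              signalToBackground =
                                sim$signal_to_background, seed = seed)
    rows <- list()
    for (id in unique(sites$transcript_id)) {
      site <- sites[sites$transcript_id == id, ][1, ]
      ev <- degradomeValidate(prof[[id]], site)
      rows[[id]] <- data.frame(
        transcript_id = id, cleavage_pos = ev@cleavage_pos,
        peak_count = ev@peak_count, category = ev@category,
        supported = ev@supported, stringsAsFactors = FALSE)
    }
    tab <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
    .write_tsv(tab, file.path(outDir, "cleavage_evidence.tsv"))
    # t-plot style table for the first validated transcript
    if (nrow(tab) > 0) {
      id <- tab$transcript_id[1]
      tp <- data.frame(position = seq_along(prof[[id]]@counts),
                       count = prof[[id]]@counts)
      tp$predicted_site <- tp$position == tab$cleavage_pos[1]
      .write_tsv(tp, file.path(outDir, "tplot_example.tsv"))
    }
    list(validated = sum(tab$supported), tested = nrow(tab))
  })

  manifest <- list(config_hash = hash, seed = seed,
                   package = as.character(utils::packageVersion("ppomir")),
                   stages_run = names(summaries))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(summaries)
}
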