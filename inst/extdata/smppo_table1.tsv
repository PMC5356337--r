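gene_name	accession	orf_bp	aa_len	pi	mw
SmPPO1	KX458045	1773	590	6.56	66010.64
SmPPO2	KX458046	1713	570	6.06	64457.11
SmPPO3	KX458047	1701	566	6.49	63976.95
SmPPO4	KX458048	1695	564	6.41	64061.26
SmPPO5	KX458049	1716	571	6.55	63827.14
SmPPO6	KX458050	1746	581	6.25	65018.72
SmPPO7	KX458051	1734	577	5.90	64231.44
SmPPO8	KX458052	1704	567	6.42	64143.58
SmPPO9	KX458053	1716	571	8.41	64190.41
SmPPO10	KX458054	1728	575	5.23	64820.16
SmPPO11	KX458055	1704	567	5.66	63326.35
SmPPO12	KX458056	1727	580	5.69	65575.18
SmPPO13	KX458057	1878	625	8.60	70294.13
SmPPO14	KX458058	1701	566	6.39	63573.64
SmPPO15	KX458059	1657	551	5.91	61922.95
SmPPO16	KX458060	1767	588	5.61	65957.20
SmPPO17	KX458061	1719	572	5.77	64851.20
SmPPO18	KX458062	1692	563	5.28	63775.88
SmPPO19	KX458063	1710	569	6.30	64738.34
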