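mag_id	taxonomy	completeness_pct	contamination_pct	has_16s	coverage	mercury_gene	n_orf	n_predicted_protein	n_genes_expressed
Bin731	Roseimarinus	87.28	5	yes	1.56	hgcAB	3827	484	2830
Bin506	Aminicenantes	57.45	2.65	no	1.03	hgcAB	4462	447	1755
Bin752	Desulforhopalus	86.41	1.52	yes	1.16	hgcAB	3543	526	2810
Bin27	Desulfobulbaceae	65.67	2.11	no	0.98	hgcAB	2613	350	1975
Bin165	Desulfatiglans	98.06	2.6	yes	1.12	hgcAB	3733	385	3428
Bin456	Desulfobacteraceae	66.32	2.82	no	0.99	hgcAB	2566	323	1935
Bin805	Desulfobacteraceae	91.61	4.27	yes	4.20	hgcAB	8173	1058	7361
Bin727	Desulfobacteraceae	88.42	4.2	no	1.10	hgcAB	5617	780	4529
Bin387	Desulfobacteraceae	54.08	1.61	no	9.42	hgcAB	3064	424	2886
Bin762	Desulfobacteraceae	53.75	1.79	no	1.13	hgcAB	3546	502	2713
Bin761	Gammaproteobacteria	89.00	3.05	no	1.34	merA	3563	424	2986
Bin495	Rhodobacteraceae	50.23	4.85	no	1.29	merA	1966	273	1149
Bin785	Rhodobacteraceae	93.64	2.7	yes	17.82	merA	3600	487	1072
Bin416	Rhodobacteraceae	50.01	1.08	no	0.80	merA	1791	215	855
Bin93	Desulfuromusa	83.87	2.1	yes	0.79	merA	2580	337	2356
Bin674	Verrucomicrobiaceae	94.76	1.16	no	5.25	merA	3036	277	2223
Bin299	Verrucomicrobiaceae	52.00	0	no	1.98	merA	2124	178	111
Bin759	Verrucomicrobiaceae	97.47	4.76	yes	2.48	merA	4343	438	2489
Bin345	Balneolaceae	90.16	2.55	no	19.83	merA	2935	327	2843
Bin55	Rubrivirga	97.27	1.37	yes	33.86	merA	3708	348	399
Bin72	Gammaproteobacteria	96.88	1.16	yes	3.76	merA	3027	302	2509
Bin660	Thiotrichaceae	96.89	2.93	yes	1.71	merB	3124	340	2371
Bin246	Rhodobacteraceae	52.53	4.55	no	5.63	merB	2507	399	1824
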