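id	allele	consequence	biotype	gene	beta_gt	p_gt	beta_gtxsex	p_gtxsex	beta_gtxla	p_gtxla
rs75297609	T	Upstream	miscRNA	RN7SKP143	-2.72	1.2e-08	3.17	2.3e-06	2.08	5.4e-03
rs57205007	G	Upstream	miscRNA	RN7SKP143	-2.13	3.7e-08	2.27	2.2e-06	1.13	2.4e-03
rs113497890	G	Intron	Protein	LCOR	-3.16	6.3e-08	3.05	1.9e-05	-0.45	6.2e-01
rs12240935	C	Upstream	miscRNA	YRNA	-3.09	1.2e-07	2.91	3.6e-03	2.36	3.9e-03
rs143615510	A	Intron	Protein	CCDC77	3.60	4.7e-07	-2.66	1.2e-03	-1.86	2.3e-02
rs79659566	A	Upstream	Protein	DYRK2	-0.92	5.5e-07	0.41	2.4e-02	0.51	2.0e-05
rs6699943	C	Intron	Protein	GLUL	1.89	6.6e-07	-1.15	1.4e-02	-2.35	3.0e-07
rs112103074	A	Intergenic	-	AC011366.3	-1.21	8.3e-07	1.47	3.6e-06	0.76	1.7e-02
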