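id	allele	chrom	pos	gene	beta_gt	p_gt	beta_gtxsex	p_gtxsex
rs7919344	T	10	92021973	RN7SKP143	-2.38	8.0e-09	2.86	4.9e-06
rs148396815	C	10	92012923	RN7SKP143	-1.87	4.2e-07	2.60	6.1e-07
10:92014488	T	10	92014488	RN7SKP143	-1.87	4.4e-07	2.35	9.2e-05
rs184996157	A	10	92018837	RN7SKP143	-1.87	4.4e-07	2.35	9.2e-05
rs534950014	G	10	92011098	RN7SKP143	-1.87	4.4e-07	2.35	9.2e-05
rs560385300	T	10	92013183	RN7SKP143	-1.87	4.4e-07	2.35	9.2e-05
rs75297609	T	10	92021574	RN7SKP143	-1.87	4.4e-07	2.35	9.2e-05
10:92016131	A	10	92016131	RN7SKP143	-1.87	4.4e-07	2.08	1.7e-04
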