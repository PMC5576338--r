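gene	platform	WT_RA	WT_HO	KO_RA	KO_HO
Gadd45a	microarray	1	3.63168	0.921811	1.002221
Gadd45a	qpcr	1	2.579674	0.908044	0.967095
Gadd45g	microarray	1	8.38319	1.43496	2.705904
Gadd45g	qpcr	1	6.245498	1.100627	2.153558
Cdkn1a	microarray	1	7.99461	1.2607	7.897151
Cdkn1a	qpcr	1	13.72415	1.537082	12.61852
Bax	microarray	1	3.87613	1.16573	2.869782
Bax	qpcr	1	3.43179	1.032757	2.079701
Serpine1	microarray	1	15.4903	1.32755	5.559448
Serpine1	qpcr	1	8.024327	0.94901	3.421921
Cdkn1b	microarray	1	0.708453	1.16238	0.75834
Cdkn1b	qpcr	1	0.740789	1.324503	1.318684
Serpina3n	microarray	1	75.388	3.72853	14.3611
Serpina3n	qpcr	1	18.49097	1.648514	4.635865
Saa3	microarray	1	5.19527	0.517552	15.89733
Saa3	qpcr	1	4.095082	0.74759	11.46964
Bmp7	microarray	1	0.907484	0.817163	1.759001
Bmp7	qpcr	1	0.821678	0.857167	3.075663
Wnt5a	microarray	1	0.2359	1.07608	0.638945
Wnt5a	qpcr	1	0.152372	0.926221	0.623315
Cdh2	microarray	1	0.642012	0.879343	0.764438
Cdh2	qpcr	1	0.199199	0.924477	0.879041
Aplnr	microarray	1	0.049004	1.06134	0.147246
Aplnr	qpcr	1	0.092198	1.04678	0.375555
S1pr1	microarray	1	2.26942	1.17521	1.116978
S1pr1	qpcr	1	4.894727	0.889052	0.87604
S1pr2	microarray	1	0.921563	0.750461	0.997753
S1pr2	qpcr	1	3.656166	0.81154	1.212284
S1pr3	microarray	1	0.933923	0.936387	1.03291
S1pr3	qpcr	1	0.415816	0.944109	0.978297
Lox	microarray	1	1.30887	1.04026	1.181007
Lox	qpcr	1	2.450447	0.932973	1.175259
Il6st	microarray	1	1.79941	1.29187	1.072552
Il6st	qpcr	1	2.79062	0.905679	0.820019
Il6	microarray	1	5.55994	1.29187	3.028182
Il6	qpcr	1	6.072546	0.791731	1.45494
Il6ra	microarray	1	1.64621	1.40755	1.136742
Il6ra	qpcr	1	2.101202	1.082853	0.876843
Sgpl1	microarray	1	0.997442	0.890375	0.938402
Sgpl1	qpcr	1	0.424413	0.963454	0.875726
Sphk1	microarray	1	3.70231	1.51325	1.556574
Sphk1	qpcr	1	4.364135	1.047004	1.149245
Lpar3	microarray	1	1.78	0.95	0.83
Lpar3	qpcr	1	2.153558	1.008994	0.773786
Chi3l3	microarray	1	26.0615	4.07383	1.2288
Chi3l3	qpcr	1	22.807	3.806	1.5576
Stfa1	microarray	1	0.0663964	0.505696	1.89924
Stfa1	qpcr	1	0.0537	0.62	2.086
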