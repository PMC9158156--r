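variant_id	risk_allele	weight	imputation_r2	is_apoe_region
rs4844610	A	0.1655	0.95	FALSE
rs6733839	T	0.2023	0.98	FALSE
rs10933431	G	0.0834	0.91	FALSE
rs9271058	A	0.0972	0.62	FALSE
rs75932628	T	0.4700	0.68	FALSE
rs9473117	C	0.0862	0.93	FALSE
rs12539172	T	0.0677	0.89	FALSE
rs10808026	A	0.0788	0.94	FALSE
rs73223431	T	0.0770	0.96	FALSE
rs9331896	C	0.1131	0.97	FALSE
rs3740688	G	0.0537	0.95	FALSE
rs7933202	C	0.0862	0.92	FALSE
rs3851179	T	0.1044	0.98	FALSE
rs11218343	C	0.2357	0.88	FALSE
rs17125924	G	0.1398	0.84	FALSE
rs12881735	C	0.0677	0.90	FALSE
rs593742	G	0.0726	0.93	FALSE
rs7185636	C	0.0770	0.86	FALSE
rs62039712	A	0.1484	0.63	FALSE
rs28394864	A	0.0677	0.91	FALSE
rs4311	A	0.0488	0.94	FALSE
rs616338	T	0.3365	0.66	FALSE
rs138190086	A	0.2151	0.61	FALSE
rs3752246	G	0.1310	0.89	FALSE
rs4147929	A	0.1222	0.92	FALSE
rs3865444	A	0.0618	0.95	FALSE
rs6024870	A	0.0834	0.87	FALSE
rs7920721	G	0.0726	0.93	FALSE
rs3740221	A	0.0583	0.85	FALSE
rs6931277	T	0.0953	0.73	FALSE
rs7657553	A	0.0629	0.90	FALSE
rs11771145	A	0.0726	0.96	FALSE
rs113260531	A	0.1133	0.71	FALSE
rs28834970	C	0.0531	0.97	FALSE
rs73572689	C	0.1054	0.78	FALSE
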