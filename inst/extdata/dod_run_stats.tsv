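run	sample	run_time_s	n_hits	hit_rate_pct	indexed_th	indexed_pk	indexed_xy	indexed_ad	indexing_rate_pct	avg_dlimit_angstrom	avg_n_peaks	avg_intensity_adu
31	thaumatin	357	1083	30.4	271	0	0	1	25.0	3.1	82	970
32	thaumatin	640	2454	38.3	1094	0	0	8	44.6	3.2	56	947
33	thaumatin	617	5604	90.9	963	0	0	4	17.2	3.0	91	920
34	thaumatin	556	3756	67.6	770	0	0	3	20.5	3.1	84	897
35	thaumatin	557	2480	44.5	726	1	0	4	29.3	3.2	64	906
36	thaumatin	660	363	5.5	266	0	0	0	73.3	3.4	27	926
37	proteinase_k	733	683	9.3	0	569	0	5	83.3	2.7	52	2149
38	proteinase_k	729	771	10.6	0	709	0	11	92.0	2.7	67	2483
39	thaumatin	438	1109	25.3	434	0	0	3	39.1	3.1	98	1117
40	thaumatin	309	2732	88.5	145	0	0	1	5.3	2.9	256	1107
42	xylanase	129	670	51.9	1	0	41	2	6.1	2.6	90	1848
43	alcohol_dehydrogenase	58	0	0	0	0	0	0	0	NA	NA	NA
44	alcohol_dehydrogenase	84	0	0	0	0	0	0	0	NA	NA	NA
45	alcohol_dehydrogenase	74	1	0.1	0	0	0	0	0	NA	17	1710
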