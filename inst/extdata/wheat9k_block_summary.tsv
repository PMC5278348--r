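chrom	total_snps	snps_in_blocks	snps_per_block_min	snps_per_block_max	tag_snps	n_blocks	mean_span_cM	span_min_cM	span_max_cM	total_haps	haps_min	haps_max
1A	419	392	2	49	187	65	1.01	0	9.42	290	2	9
1B	295	275	2	20	177	69	0.69	0	5.31	284	2	11
2A	304	281	2	34	134	52	1.29	0	10.72	220	2	13
2B	529	491	2	37	261	96	1.12	0	8.71	410	2	25
3A	340	320	2	23	162	53	1.35	0	12.08	232	2	12
3B	373	328	2	24	209	79	0.69	0	5.86	332	1	10
4A	315	287	2	48	117	43	1.84	0	11.45	168	2	9
4B	140	125	2	10	81	29	1.52	0	13.61	126	2	8
5A	357	330	2	27	171	65	1.10	0	6.06	277	2	14
5B	472	441	2	35	215	77	1.20	0	10.24	335	2	8
6A	342	331	2	56	132	47	1.86	0	10.64	212	2	11
6B	351	314	2	52	185	70	0.77	0	6.24	279	2	13
7A	343	319	2	16	182	81	0.72	0	7.39	290	2	7
7B	236	214	2	11	134	52	1.06	0	8.09	216	2	9
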