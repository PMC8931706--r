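dataset	n_sequences	model	omega	lnL	np	compared_to	published_stat	published_p
I	119	A	0.06834	-39769.38	238	NA	NA	NA
I	119	B	1	-45248.02	237	A	10957.28	0
I	119	C	0.06586;0.25874	-39738.10	239	A	62.56	2.55E-15
I	119	D	0.06584;1	-39767.96	238	C	59.72	1.10E-14
I	119	E	NA	-39473.34	473	C	529.52	0
II	113	A	0.06227	-39175.69	226	NA	NA	NA
II	113	B	1	-44932.98	225	A	11514.58	0
II	113	C	0.06238;0.05961	-39175.65	227	A	0.08	7.71E-01
II	113	D	0.06179;1	-39383.37	226	C	415.44	0
II	113	E	NA	-38990.45	449	C	370.40	0
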