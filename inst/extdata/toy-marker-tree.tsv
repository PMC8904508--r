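branch	parent	chrom	site	ancestral	derived
O1	root	Y	2650001	C	T
O1	root	Y	2650002	A	G
O2	O1	Y	2650003	A	G
O3	O2	Y	2650004	A	G
D	root	Y	2650005	A	C
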