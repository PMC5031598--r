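motifs_per_gene	n_genes
1	85
2	107
3	92
4	75
5	58
6	45
7	32
8	20
9	13
10	5
11	6
12	5
15	1
16	1
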