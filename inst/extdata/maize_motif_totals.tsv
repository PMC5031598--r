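key	value
genic_motifs_total	3423
motifs_in_genes	2143
motif_genes	544
cds_motifs	1909
cds_count	811
cds_motif_genes	511
non_cds_motifs	234
intron_nt_per_kb_cds	1153.7
frame1_motifs	868
frame2_motifs	389
frame3_motifs	1094
n_genes_genome	39656
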