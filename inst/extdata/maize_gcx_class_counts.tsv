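gcx	n_high	n_low
GC1	3647	36009
GC2	629	39027
GC3	5719	33937
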