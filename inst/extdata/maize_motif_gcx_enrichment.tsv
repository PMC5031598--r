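gcx	observed_high	observed_low	reported_p
GC1	130	414	1.79998E-32
GC2	28	516	2.97987E-11
GC3	227	317	1.87802E-73
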