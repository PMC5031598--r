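class	gcx	observed_low	observed_high	reported_p
all_expressed	GC1	22023	2184	0.3477
all_expressed	GC2	23852	355	0.1363
all_expressed	GC3	20648	3559	0.2136
up_vs_anthers	GC1	180	9	0.0349
up_vs_seedlings	GC1	3002	234	1.0900E-04
down_vs_anthers	GC1	192	40	2.2300E-05
down_vs_seedlings	GC1	3560	580	8.5100E-27
up_vs_anthers	GC2	186	4	0.5596
up_vs_seedlings	GC2	3200	36	3.1000E-02
down_vs_anthers	GC2	224	8	2.3200E-02
down_vs_seedlings	GC2	4029	111	1.7100E-08
up_vs_anthers	GC3	179	10	0.0004
up_vs_seedlings	GC3	2855	381	1.7800E-05
down_vs_anthers	GC3	167	65	3.7800E-09
down_vs_seedlings	GC3	3117	1023	3.6400E-79
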