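within	gcx	observed_high	observed_low	reported_p
GC1	GC2	26	3621	2.43E-05
GC1	GC3	96	3551	2.57E-91
GC2	GC1	26	603	1.11E-05
GC2	GC3	26	603	2.06E-13
GC3	GC1	96	5623	3.59E-86
GC3	GC2	26	5693	7.44E-12
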