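direction	comparison	observed_yes	observed_no	reported_p
up	anther	2	542	0.712147988
up	seedling	18	526	3.57589E-05
down	anther	2	542	0.506157854
down	seedling	62	482	0.465276348
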