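metric	kind	a	b	digits	rounding
somatic_sensitivity	sensitivity	252	2	2	round
somatic_specificity	specificity	27720810	1	2	floor
germline_sensitivity	sensitivity	80	0	2	round
germline_specificity	specificity	229050	0	2	round
msi_sensitivity	sensitivity	51	2	2	floor
msi_specificity	specificity	53	0	2	round
loh_sensitivity	sensitivity	32	3	1	round
loh_sensitivity_excl_het	sensitivity	152	0	1	round
loh_specificity	specificity	123	1	1	round
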