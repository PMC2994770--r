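locus	threshold	naB	nAb	nb	nB
cytb	2.5	225	0	444962	456191
cytb	2.0	219	0	444968	456185
cytb	1.5	90	0	445097	456056
coi	2.5	281	0	444906	456247
coi	2.0	223	0	444964	456189
coi	1.5	216	0	444971	456182
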