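feature	cohort	carriers	n
G25	AL	33	137
G25	MM	0	9
G25	OAS	5958	90110
nonR25	AL	38	137
nonR25	MM	1	9
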