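dimension	level	decrement
MO	2	0.056
MO	3	0.247
SC	2	0.049
SC	3	0.233
UA	2	0.043
UA	3	0.223
PD	2	0.061
PD	3	0.252
AD	2	0.052
AD	3	0.245
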