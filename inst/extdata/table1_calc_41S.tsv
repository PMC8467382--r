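label	j_mean
H40a/H41	2.3
H40b/H41	9.7
H41/H42a	4.5
H41/H42b	6.0
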