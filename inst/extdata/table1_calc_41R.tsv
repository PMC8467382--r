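label	j_mean
H40a/H41	3.8
H40b/H41	8.7
H41/H42a	3.1
H41/H42b	9.2
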