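territory	ac_mean	ac_sd
RMCA	0.57	0.20
LMCA	0.50	0.30
ACA	0.43	0.24
RPCA	1.1	0.48
LPCA	1.1	0.30
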