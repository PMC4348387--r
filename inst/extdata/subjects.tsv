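subject	age	sex	bp_sys	bp_dia	pp	heart_rate_bpm	slice_above_cow
I	28	M	122	56	66	59.8	4
II	24	M	119	62	57	50.6	4
III	25	F	108	66	42	71.7	3
IV	25	F	110	64	46	69.5	3
V	25	M	119	66	53	75.2	4
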