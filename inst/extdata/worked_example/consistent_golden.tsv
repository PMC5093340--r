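feature_id	event	direction	n_cancers	cancers	min_p
F01	DRIVER1	up	2	A,B	0.000619654567738768
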