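feature_id	event	cancer	p_value	log2_ratio	n_mut	n_wt	detectable	passes
F01	DRIVER1	A	0.000619654567738768	2.96777705170872	6	14	TRUE	TRUE
F02	DRIVER1	A	0.342872930489716	-0.0144302601504291	6	14	TRUE	FALSE
F03	DRIVER1	A	0.265510388953874	-0.00812375000845017	6	14	TRUE	FALSE
F04	DRIVER1	A	0.127046158376808	-0.00489457007411439	6	14	TRUE	FALSE
F05	DRIVER1	A	0.00481510680543824	-0.00293205606483162	6	14	TRUE	FALSE
F06	DRIVER1	A	0.00164468405415459	-0.00161312444135626	6	14	TRUE	FALSE
F07	DRIVER1	A	0.967105119498331	-0.000665789542261997	6	14	TRUE	FALSE
F08	DRIVER1	A	1	4.75988441205077e-05	6	14	TRUE	FALSE
F09	DRIVER1	A	0.836637402400589	0.000604176763944408	6	14	TRUE	FALSE
F10	DRIVER1	A	0.000522771306051238	-16.9417157253481	6	14	FALSE	FALSE
F01	DRIVER1	B	0.000619654567738768	2.98292468266168	6	14	TRUE	TRUE
F02	DRIVER1	B	0.650093462348504	-0.00827511343598756	6	14	TRUE	FALSE
F03	DRIVER1	B	0.483260464590643	-0.00515158262426878	6	14	TRUE	FALSE
F04	DRIVER1	B	0.302548968453419	-0.00355113907820962	6	14	TRUE	FALSE
F05	DRIVER1	B	0.0204283813549241	-0.00257812571405299	6	14	TRUE	FALSE
F06	DRIVER1	B	0.0135265428877107	-0.00192405022527366	6	14	TRUE	FALSE
F07	DRIVER1	B	0.591881862930254	-0.0014541801727952	6	14	TRUE	FALSE
F08	DRIVER1	B	0.772829992684448	-0.00110030467007498	6	14	TRUE	FALSE
F09	DRIVER1	B	0.836637402400589	-0.000824190421816345	6	14	TRUE	FALSE
F10	DRIVER1	B	0.000522771306051238	-16.932644101643	6	14	FALSE	FALSE
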