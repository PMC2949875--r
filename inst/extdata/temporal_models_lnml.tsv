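model	lnml	se
Para45_Liot45	-14285.01	0.19
Para35_Liot35	-14287.19	0.15
Para25_Liot25	-14288.99	0.17
Para45_Liot35	-14286.54	0.16
Para35_Liot45	-14287.86	0.17
Para35_Liot25	-14291.33	0.15
Para25_Liot35	-14288.09	0.17
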