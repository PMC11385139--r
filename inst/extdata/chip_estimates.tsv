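trait	abbreviation	n_individuals	h2	h2_se	rg_milk	rg_milk_se
Milk yield	MY	34497	0.4358	0.0078	NA	NA
Interdigital hyperplasia	IH	30968	0.1530	0.0069	-0.1059	0.0271
Digital phlegmon	PH	26437	0.0980	0.0062	-0.1816	0.0319
Claw ulcers	CU	27012	0.1530	0.0072	-0.0685	0.0280
Digital dermatitis	DD	30056	0.1747	0.0072	-0.0187	0.0262
Mastitis	MAS	33298	0.1326	0.0063	-0.3030	0.0261
Metritis	MET	27283	0.0558	0.0048	-0.0111	0.0387
Retained placenta	RP	28182	0.0738	0.0053	-0.0878	0.0349
Cyclus disturbances	CD	26884	0.0771	0.0055	-0.1970	0.0341
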