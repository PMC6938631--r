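variant_id	gene	classification	classification_basis	assay_instance_id	readout_value	readout_units
B1	GENE1	B	BA1	inst1	62.310101666487753	percent_wildtype
B1	GENE1	B	BA1	inst2	63.936757617630064	percent_wildtype
B2	GENE1	LB	BS1;BP4	inst1	71.936526171863079	percent_wildtype
B2	GENE1	LB	BS1;BP4	inst2	72.55363930342719	percent_wildtype
B3	GENE1	B	BS1	inst1	77.815771482419223	percent_wildtype
B3	GENE1	B	BS1	inst2	78.077594297006726	percent_wildtype
B4	GENE1	LB	BA1;BP7	inst1	84.413775327149779	percent_wildtype
B4	GENE1	LB	BA1;BP7	inst2	84.374207110609859	percent_wildtype
B5	GENE1	LB	BS1;BP4	inst1	89.559939376078546	percent_wildtype
B5	GENE1	LB	BS1;BP4	inst2	88.387887854129076	percent_wildtype
B6	GENE1	LB	BA1	inst1	45	percent_wildtype
P1	GENE1	P	PVS1;PM2	inst1	12	percent_wildtype
P1	GENE1	P	PVS1;PM2	inst2	15	percent_wildtype
P1	GENE1	P	PVS1;PM2	inst3	70	percent_wildtype
P2	GENE1	LP	PS4;PM2;PP3	inst1	7.8684623567387462	percent_wildtype
P2	GENE1	LP	PS4;PM2;PP3	inst2	7.0045490362681448	percent_wildtype
P3	GENE1	P	PVS1;PM2;PP3	inst1	18.669384277425706	percent_wildtype
P3	GENE1	P	PVS1;PM2;PP3	inst2	18.660165932495147	percent_wildtype
P4	GENE1	P	PS4;PM1;PM2	inst1	22.913935635704547	percent_wildtype
P4	GENE1	P	PS4;PM1;PM2	inst2	22.896994146052748	percent_wildtype
P5	GENE1	LP	PVS1;PS4	inst1	27.201459951233119	percent_wildtype
P5	GENE1	LP	PVS1;PS4	inst2	26.523614809848368	percent_wildtype
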