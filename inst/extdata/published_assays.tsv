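# Validated hydrolysis-probe assays for marine eDNA detection.
# Oligo names encode the 1-based 5' coordinate on the design accession
# (humpback: GQ353077.1 d-loop; rockfish: JQ354411 COI; murre: GU572157.1 COI).
assay	species	gene	accession	oligo_name	role	sequence	reporter	quencher	conc_uM	ta_C	cq_threshold	target_length_nt
humpback	Megaptera novaeangliae	d-loop	GQ353077.1	287F	forward	GCCGCTCCATTAGATCACGA			0.2	60	0.01	151
humpback	Megaptera novaeangliae	d-loop	GQ353077.1	362P	probe	TCGCACCGGGCCCATCAATCGT	FAM	BHQ	0.1	60	0.01	151
humpback	Megaptera novaeangliae	d-loop	GQ353077.1	437R	reverse	TGGCCCTGAAGTAAGAACCAG			0.2	60	0.01	151
rockfish	Sebastes jordani	COI	JQ354411	169F	forward	CAGGAGCATCAGTCGACCTG			0.2	60	0.02	176
rockfish	Sebastes jordani	COI	JQ354411	294P	probe	ACACCCTTATTTGTGTGGGCCGTCCT	FAM	BHQ	0.1	60	0.02	176
rockfish	Sebastes jordani	COI	JQ354411	344R	reverse	GAGAAGGAGAAGGACAGCGG			0.2	60	0.02	176
murre	Uria aalge	COI	GU572157.1	9F	forward	TGGCGCATGAGCTGGTATAG			0.2	64	0.02	130
murre	Uria aalge	COI	GU572157.1	34P	probe	ACCGCCCTAAGCCTGCTCATCCGT	FAM	BHQ	0.2	64	0.02	130
murre	Uria aalge	COI	GU572157.1	138R	reverse	TATTACAAAGGCGTGGGCGG			0.2	64	0.02	130
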