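# reference panel: proteins reported as cross-platform regulated in mouse MS-model frontal cortex
# q-value columns encode the published significance category as an upper bound (q < bound); empty = not significant
accession	protein	tmt_fc_CPZ-42d	tmt_qmax_CPZ-42d	tmt_fc_EAE-16d	tmt_qmax_EAE-16d	tmt_fc_EAE-32d	tmt_qmax_EAE-32d	lf_fc_CPZ-42d	lf_qmax_CPZ-42d	lf_fc_EAE-16d	lf_qmax_EAE-16d	lf_fc_EAE-32d	lf_qmax_EAE-32d	hcsf	hplasma
O89017	LGMN	4.0	0.0005	0.7		0.7		4.9	0.05	1.9		1.3		Y	N
P14106	C1QB	5.3	0.0005	0.8		0.8		19.4	0.01	1.5		1.3		Y	Y
Q02105	C1QC	5.3	0.0005	0.8		0.8		9.1	0.01	1.2		1.3		Y	Y
P98086	C1QA	3.8	0.0005	0.9		0.9		6.8	0.01	1.1		1.1		Y	Y
P03995	GFAP	2.6	0.0005	1.3		1.1		7.2	0.01	1.5		1.0		Y	N
Q5EBJ4	ERMIN	0.5	0.0005	1.3		1.1		0.5	0.01	0.9		0.8		Y	N
Q91X72	HEMO	0.9		1.8	0.0005	1.2		0.9		3.3	0.05	1.5		Y	Y
P07758	A1AT	1.0		1.7	0.0005	1.2		0.9		4.4	0.05	1.8		Y	Y
P97772	GRM1	1.1		0.7		0.7	0.05	1.8		0.5		0.5	0.1	N	Y
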