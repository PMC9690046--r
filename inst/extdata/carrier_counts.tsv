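# Carrier counts reported in a published breast-cancer mtDNA case-control
# comparison (cases vs. healthy-tissue controls). Denominators differ by row
# because partial (HVR) sequences cover only part of the genome.
region	label	dbsnp	case_carriers	case_total	control_carriers	control_total
HVR2	m.310del	rs869289246	27	78	21	34
HVR2	m.310T>C	rs1556422421	4	78	0	34
HVR2	m.310delinsCCTC	rs46492218	1	78	1	34
HVR2	m.315dup	rs369786048	47	78	13	34
MT-ND3	m.10398A>G	rs2853826	9	50	10	34
HVR1	m.16183A>C	rs28671493	10	78	5	34
HVR1	m.16189T>C	rs28693675	17	90	9	34
HVR1	m.16311T>C	rs34799580	11	90	8	34
control	m.16519T>C	rs3937033	34	66	20	34
MOTS-c	m.1346A>G	rs879104061	1	52	0	34
Humanin	m.2706A>G	rs2854128	32	52	26	34
SHLP2	m.2124A>G	-	1	52	0	34
SHLP2	m.2145del	-	1	52	0	34
SHLP3	m.1709A>G	rs200251800	2	52	4	34
SHLP3	m.1716A>G	rs1556422559	1	52	2	34
SHLP3	m.1719A>G	rs3928305	7	52	2	34
SHLP3	m.1736A>G	rs193303006	2	52	4	34
SHLP3	m.1811A>G	rs28358576	1	52	1	34
SHLP4	m.2445A>G	-	1	52	0	34
SHLP6	m.3010A>G	rs3928306	11	52	6	34
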