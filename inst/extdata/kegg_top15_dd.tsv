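set_id	name	p_value	count	gene_ids
hsa05031	Amphetamine addiction	7.39e-09	4	MAOB,MAOA,CACNA1C,CAMK2A
hsa04726	Serotonergic synapse	5.65e-08	4	MAOB,APP,CACNA1C,MAOA
hsa04728	Dopaminergic synapse	9.39e-08	4	MAOB,MAOA,CACNA1C,CAMK2A
hsa00330	Arginine and proline metabolism	6.34e-07	3	MAOB,NOS2,MAOA
hsa04066	HIF-1 signaling pathway	6.10e-06	3	NOS2,VEGFA,CAMK2A
hsa00360	Phenylalanine metabolism	1.64e-05	2	MAOB,MAOA
hsa04934	Cushing syndrome	1.71e-05	3	CRH,CACNA1C,CAMK2A
hsa05034	Alcoholism	2.65e-05	3	MAOB,CRH,MAOA
hsa00340	Histidine metabolism	2.88e-05	2	MAOB,MAOA
hsa04020	Calcium signaling pathway	3.25e-05	3	NOS2,CACNA1C,CAMK2A
hsa00350	Tyrosine metabolism	6.73e-05	2	MAOB,MAOA
hsa01100	Metabolic pathways	6.98e-05	5	MAOB,NOS2,AR,MAOA,GAD2
hsa00260	Glycine, serine, and threonine metabolism	8.23e-05	2	MAOB,MAOA
hsa00380	Tryptophan metabolism	9.04e-05	2	MAOB,MAOA
hsa05030	Cocaine addiction	1.22e-04	2	MAOB,MAOA
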