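compound_id	name	formula	mw	hbd	hba	logp	gi_class	literature_override
HF01	(-)-(1S,3S)-1-Methyl-1,2,3,4-tetrahydro-beta-carboline-3-carboxylic acid	C13H14N2O2	230.3	3	3	1.2	high	FALSE
HF02	(+)-Dehydrovomifoliol	C13H18O3	222.3	1	3	1.2	high	FALSE
HF03	(3S,5R)-Butyl-3-hydroxy-2-oxopyrrolidine-5-carboxylate	C9H15NO4	201.2	2	4	0.2	high	FALSE
HF04	(S)-2,4-Dibutoxy-3-(hydroxymethyl)cyclopent-2-en-1-one	C14H24O4	256.3	1	4	2.4	high	FALSE
HF05	(S)-Abscisic acid	C15H20O4	264.3	2	4	1.9	high	FALSE
HF06	2'-Deoxyadenosine	C10H13N5O3	251.1	3	7	-1.2	high	FALSE
HF07	5,6-Epoxy-3-hydroxy-7-megastigmen-9-ene	C13H20O3	224.3	1	3	1.7	high	FALSE
HF08	5-O-p-Coumaroyl-1,5-quinide lactone	C16H16O7	320.3	3	7	0.9	high	FALSE
HF09	5-O-p-Coumaroylquinic acid butyl ester	C20H26O8	394.4	4	8	1.9	high	FALSE
HF10	5-O-p-Coumaroylquinic acid methyl ester	C17H20O8	352.3	4	8	0.7	high	FALSE
HF11	Apigenin	C15H10O5	270.3	3	5	2.6	high	FALSE
HF12	Catechin	C15H14O6	290.1	5	6	1.5	high	FALSE
HF13	Chlorogenic acid	C16H18O9	354.3	6	8	-0.65	low	TRUE
HF14	Chrysin	C15H10O4	254.3	2	4	3.0	high	FALSE
HF15	Daidzein	C15H10O4	254.3	2	4	2.6	high	FALSE
HF16	Dehydrololiolide	C11H14O3	194.2	0	3	1.2	high	FALSE
HF17	Ellagic acid	C14H6O8	302.2	4	8	1.1	high	FALSE
HF18	(-)-Epicatechin	C15H14O6	290.1	5	6	1.5	high	FALSE
HF19	Epigallocatechin gallate	C22H18O11	458.4	8	11	2.23	low	TRUE
HF20	Fulvanine D	C10H15NO5	229.2	3	5	-1.0	high	FALSE
HF21	Galangin	C15H10O5	270.3	3	5	2.9	high	FALSE
HF22	Hemerocallisamine I	C13H18N2O6	298.3	4	6	-1.3	high	FALSE
HF23	Hemerocallisamine II	C10H15NO2	181.2	2	2	0.8	high	FALSE
HF24	Hemerocallisamine III	C10H15NO4	213.2	3	4	-0.6	high	FALSE
HF25	Hemerocallisamine IV	C10H15NO4	213.2	3	4	-0.6	high	FALSE
HF26	Hemerocallisamine V	C9H13NO4	199.2	3	4	-0.8	high	FALSE
HF27	Hemerocallisamine VI	C9H11NO4	197.2	3	4	-0.9	high	FALSE
HF28	Hemerocallisamine VII	C11H17NO5	243.2	3	5	-1.1	high	FALSE
HF29	Hesperidin	C28H34O15	610.6	8	15	-1.16	low	TRUE
HF30	Hydroxydihydrobovolide	C11H18O3	198.3	1	3	1.4	high	FALSE
HF31	Isololiolide	C11H16O3	196.3	1	3	0.9	high	FALSE
HF32	Kaempherol	C15H10O6	286.25	4	6	1.9	high	FALSE
HF33	Linoleic acid	C18H32O2	280.5	1	1	5.88	high	TRUE
HF34	Loliolide	C11H16O3	196.3	1	3	0.9	high	FALSE
HF35	Longitubanine A	C10H16N2O5	244.3	4	6	-1.5	high	FALSE
HF36	Longitubanine B	C10H16N2O4	228.3	3	5	-1.2	high	FALSE
HF37	Luteolin	C15H10O6	286.0	4	6	2.5	high	FALSE
HF38	Lycoperodine-1	C12H12N2O2	216.2	3	3	1.1	high	FALSE
HF39	Methyl 2,4-dihydroxy-6-(4-hydroxyphenethyl)-3-methylbenzoate	C17H18O5	302.3	3	5	3.1	high	FALSE
HF40	Morin	C15H10O7	302.3	5	7	1.6	high	FALSE
HF41	Myricetin	C15H10O8	318.3	6	8	1.69	low	TRUE
HF42	Naringenin	C15H12O5	272.3	3	5	2.4	high	FALSE
HF43	Naringin	C27H32O14	580.6	8	14	-1.17	low	TRUE
HF44	Pinocembrin	C15H12O4	256.3	2	4	2.6	high	FALSE
HF45	Prunasin	C14H17NO6	295.3	4	7	-0.7	high	FALSE
HF46	Pseudolaroside C	C14H18O8	314.3	5	8	-1.3	high	FALSE
HF47	Quercetin	C15H10O7	302.3	5	7	1.99	high	FALSE
HF48	Quercetin-3-O-rutinoside	C27H30O16	610.5	10	16	-1.69	low	TRUE
HF49	Quercetin-3-O-beta-D-galactopyranoside	C21H20O12	464.4	8	12	-0.54	low	TRUE
HF50	Quercetin-3-O-beta-D-glucopyranoside	C21H20O12	464.4	8	12	-0.54	low	TRUE
HF51	Rosin	C15H20O6	296.3	4	6	-0.8	high	FALSE
HF52	Salidroside	C14H20O7	300.3	5	7	-1.1	high	FALSE
HF53	Vitexin	C21H20O10	432.4	7	10	0.09	low	TRUE
HF54	Wogonin	C16H12O5	284.3	2	5	3.0	high	FALSE
HF55	alpha-Linolenic acid	C18H30O2	278.4	1	1	5.66	high	TRUE
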