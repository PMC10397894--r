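country	site	year	latitude	longitude	n_total	n_female	n_male
Burkina Faso	Bana	2012	11.2330	-4.4720	20	3	17
Burkina Faso	Pala	2012	11.1500	-4.2350	46	38	8
Burkina Faso	Souroukoudinga	2012	11.2350	-4.5350	26	26	0
Cameroon	Daiguene	2009	4.7770	13.8440	96	81	15
Cameroon	Gado Badzere	2009	5.7470	14.4420	73	58	15
Cameroon	Mayos	2009	4.3410	13.5580	105	91	14
Cameroon	Zembe Borongo	2009	5.7470	14.4420	23	23	0
Equatorial Guinea	Bioko	2002	3.7000	8.7000	9	9	0
France (Mayotte)	Bouyouni	2011	-12.7378	45.1417	1	1	0
France (Mayotte)	Combani	2011	-12.7787	45.1429	5	2	3
France (Mayotte)	Karihani Lake	2011	-12.7965	45.1217	3	3	0
France (Mayotte)	Mont Benara	2011	-12.8570	45.1552	2	1	1
France (Mayotte)	Mtsamboro Forest Reserve	2011	-12.7027	45.0811	1	1	0
France (Mayotte)	Mtsanga Charifou	2011	-12.9907	45.1557	8	3	5
France (Mayotte)	Sada	2011	-12.8521	45.1039	4	1	3
Gabon	Libreville	2000	0.3840	9.4550	69	69	0
Ghana	Madina	2012	5.6685	-0.2193	12	12	0
Guinea	Koraboh	2012	9.2500	-9.9170	22	22	0
Guinea	Koundara	2012	8.5000	-9.4170	18	18	0
Uganda	Tororo (Nagongera)	2012	0.7700	34.0260	112	112	0
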