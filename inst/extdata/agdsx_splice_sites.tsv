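kind	gender	ordinal	element_size	element_start	element_end	site_start	site_end	sequence
donor	Male/Female	1	1415	48788460	48787046	48787051	48787030	tatttg/gtaagtaaatatgcaa
donor	Male/Female	2	1445	48785629	48784185	48784190	48784169	TGGGAG/gtaagtacgatcatgc
donor	Male/Female	3	45	48747737	48747693	48747698	48747677	TACCTG/gtaagtaaatataatt
donor	Male/Female	4	135	48715295	48715161	48715166	48715145	ACGAAG/gtaagctggcgatgat
donor	Female	5	1692	48714648	48712957	48712962	48712941	cagaag/gtatggtaagacggcc
donor	Male/Female	6	1267	48712794	48711528	48711533	48711512	aaaaag/gtaagtgtgggtagta
acceptor	Male/Female	1	1416	48787045	48785630	48785645	48785624	gtacgtttgattgcag/atctcc
acceptor	Male/Female	2	36447	48784184	48747738	48747753	48747732	ttgctctccttttcag/CTACTC
acceptor	Male/Female	3	32397	48747692	48715296	48715311	48715290	ttccgccccgtttcag/ACGACG
acceptor	Female	4	512	48715160	48714649	48714664	48714643	tttatgtttaacacag/GTCAAG
acceptor	Male	4	2366	48715160	48712795	48712810	48712789	tgtaacccccaaaaag/gtaaac
acceptor	Male/Female	6	5196	48711527	48706332	48706347	48706326	cgcttcctcaaaatag/atcgat
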