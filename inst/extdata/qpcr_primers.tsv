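gene	direction	sequence	product_length
Cacna2d1	forward	AGTTTATCCCAAAGAGGCCG	149
Cacna2d1	reverse	TTCCAGATTCATACGCACCAG	149
Grin2a	forward	TGGTGATCGTGCTGAATAAGG	147
Grin2a	reverse	AGGTGACAATGCTGAGGTG	147
Npy1r	forward	GCCCACTCTGCTTTATATTCATATG	108
Npy1r	reverse	ATTCGCTTGGTCTCACTGG	108
Mef2c	forward	CCAGATCTCCGCGTTCTTATC	149
Mef2c	reverse	CCTCCCATTCCTTGTCCTG	149
Epha4	forward	TCGTTATGTGGGAAGTGATGTC	133
Epha4	reverse	AACTGATGGAGGGCAATGG	133
Rxfp1	forward	TGTGCTGGATTCCCATCTTC	148
Rxfp1	reverse	AAAGGTCTAGTGGTCAACGTG	148
Chrm3	forward	TCGGTAGAGCGGACTGG	148
Chrm3	reverse	TTCACTCAATCCACAGTCCAC	148
Pde1a	forward	TGCTATTCTGTACAACGACCG	148
Pde1a	reverse	GACCATTTCAATCACTAAGTTCCG	148
Atp2b4	forward	GGATTGGAGAACTTTTGTGGG	145
Atp2b4	reverse	ATCTCGGCAAGGTCAATCTC	145
Glra1	forward	GGAAGAGAAAGACCTGAGATACTG	144
Glra1	reverse	GACAGGATGACGATGAGCAG	144
Idi1	forward	ATTGGTGTGAAGCGAGCA	133
Idi1	reverse	CACCCCAGATACCATCAGATTG	133
Fgf1	forward	TGGGACAAGGGACAGGAG	150
Fgf1	reverse	TCCTCATTTGGTGTCTGCG	150
Grin2b	forward	AAGGAGAGGAAGTGGGAGAG	128
Grin2b	reverse	AAGGTAACGATGCTCAGATGG	128
Cda	forward	CTGCCGACAAGTCATGAGAG	122
Cda	reverse	GGTCTTCAGGTCCAAACGAG	122
Actb	forward	ACCTTCTACAATGAGCTGCG	146
Actb	reverse	CTGGATGGCTACGTACATGG	146
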