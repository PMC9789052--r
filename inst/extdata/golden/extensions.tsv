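transcript_id	gene_id	ext_start	length_codons	boundary	win_start	win_codons	win_seq
TX0001	GENE0001	4	72	stop_bounded	70	50	ATTGCTTTGGCCGAAAATCTAGGCGATATTTCTATTTCGCTAGAAGAGTGCTTCATTTGGCGTTTGTGTGGATGTCGTCAGCTGGAGATTTCTCCACGTTTTCATGTTGACAATCCGCAATTGCGTGAATATATTCTCGTTCAGTGCCAA
TX0002	GENE0002	3	58	stop_bounded	27	50	GGAATTGATGATGACTGGGCCGGCCCCCTGGGGGGTTCTCACAAGTCATTGTTTTGTACAGGCGCCACTCACAGGGTAATTAACCGTGTCAGGACCGTCACACAAGTGAACAAACACCTCCGTAGTTCGGAAGATTTCCCCGATAGGGGC
TX0003	GENE0003	5	105	stop_bounded	170	50	TCGCTACGCCCCGTACTATATACTCTTGAATCGACCCCGGGATACTGGAGTCACGCGGGTAAAGACTTAACTCCCACCGGGGTATCAACGTCACAGGAAGGTCAGCATCGGACTAGTCTTCGTCTACAAAACGTGTCTCCGCTCGATCCA
TX0004	GENE0004	5	94	stop_bounded	137	50	TGCTGTGATTTACCAGGGACCGAGCGTGACTGTCTTCGTTTGATAGTTGGACAAAATGTTGCCCATCGCGGAGTCAGGACTCAATACCTCGCCTACACTTGGCCTCTATCGGGCTACAAATTCCAGAATGGACATTACTATAACGCGGTA
TX0005	GENE0005	3	44	stop_bounded	3	44	GTACACACAAGGGAGAGATGGACCTGCTTTCGCCTGTTGGCTCTGAGGCAACACTCTCTGTCTAGATGTTTACTCTCGATATGTAACAATCGCTCGCGGAAAGTCCCGCCTAGAGGATGGCTAGACGAAACT
TX0007	GENE0007	5	119	stop_bounded	212	50	CTTTGCATAGTGACTAAGCAGACAGCCGAGCTTGTGTCTTCCTATAGCAGGTATCCGGGGCTACGGAATATTTCCAGCTGTTCAAACATCGCGCAGAGGCAGAGCCCCTATTCGGGAAGCCGTAACGCTAAACCCGAGAGGCCATGGGCG
TX0008	GENE0008	5	75	stop_bounded	80	50	CCGGTAATCTCCGTTTTAATACGTACACTGAATACTCGTTCTAGTGTGGGTCTGATTAGTGTTGACCTCAGACCTTTCCAGTCGACGGTCCAGTATAGTCTGCTGCCCACTCTGGGCCGGGGTCATCGACCTGGACAGCACTACACTGCG
TX0009	GENE0009	5	70	stop_bounded	65	50	TCGAGGGGTCATCCGGCCACCGGTCTGTGTTACACACGAACGTACCATATTGCCGGCCTATCTGGAGCATGGAGAACGAAGCCTTGTAAAGGAAAATTTGATTATACGCAAATATTCCAGTTGGGGAACGACTTATTTGGCCTAGACATA
TX0010	GENE0010	3	59	stop_bounded	30	50	CATAGCCCGCCTTCGTGTGAAGCGTGTTCACCTGTTACGAGTTCGCTATGGCGCCCACAAGTGCAAACCTGGGATCACTCAAGTTCTAACCCGTTATGTGGAGCCTCCACACCAAGCTGTACAAAGTCCAAACGGGCGAGGAAACCGTTG
TX0011	GENE0011	5	43	stop_bounded	5	43	TCGAGAATAAATCCTGCGCATTATGAAGGAGATCTATGGATAAAAGACTCTAACCAACACGCGATATACTTCGTTGGTCAGACATTTGACCACCTGGCACTGAACACTGCCTCTCGGGAAGTCCCCAGT
TX0012	GENE0012	3	42	stop_bounded	3	42	TTGAACGGTTCCCTCTCGTTGCGTCTGAATAAATCAGGATGGCACCATTTCAGGCGTATCAGCTACAAGGGAGCCCCCACTCGGGGTTACGGTGGAGTTAATAATTCTGGAGCTCTGGATTTAAAG
TX0013	GENE0013	3	58	stop_bounded	27	50	GAGCGGTCATTGATTACATTTCCATATCGTCCCGAGCTCAACGTGGCTAAAGTCAGGAGGTGTTTACTCTTAAGGACAAGCCGGAGAGCGACGAGTCCACGCCCACATTCCGATACTTTAGCTTTACCTCCCCAAGGTCGTGGTAAAAAT
TX0015	GENE0015	3	62	stop_bounded	39	50	CCCTTAACTAAGTCCTGCACAAACCAAAATGTAAATTGGCGGAGAGTGAACTTTCTCATAAGAGTTGGCCCAGTCGGGCAGTTAGTGTTAATTATTCGCCCAAATGATTGTCGCCGTCATGACGGAGATCAGGCGCGACTAGGGGCCTCA
TX0016	GENE0016	4	58	stop_bounded	28	50	GCCTTCATCACTGCCACGGGCTGCAAGAACAAGGATCGTTTGGTACTGGACTTTGGGGACTTAGGCGGATGGCCTTCGCTAAGCCAAGGCCCCCGTAAGTTTTCAGACCGTGGCACGAATGACGTGCTATGGGCTGTCCGTTTTACAAGC
TX0017	GENE0017	3	90	stop_bounded	123	50	GACGGAGGTTTTGATGTTTCATCTTTAGCCCGTACGGGCCATCGATACAGATCGCAAGTCAATAGGAGCCGCGCCCCATCCGGACGGAGCTCCGTCATTTGTCCGTTGACCAGGCGTCATAACTGCTGTGACGGACAGAAGCAAGTCTTT
TX0018	GENE0018	5	41	stop_bounded	5	41	TGGTACCAGCGCATCGTCAGCATAAGGCCGCGTTTTTGCTGCAAACTTTACGAGAATACATCAACTTGTGCGTTTGACGCTGCTGACGGTGTACCAATAAATAGATACGGTTGTCAATTCCCT
TX0019	GENE0019	5	69	stop_bounded	62	50	GAATTAGCGGTGGCCAGCAACTTAAGGAGACAGCTCGTACCTTGCGAATGCACGCAACTCTCTTTAGATCGATACGCATATCATAGGGCACCTTTGTCATCGTCTCTCCACATAATCGCCTCACATTATTGGATATCCTCGAGCAGCCTG
TX0020	GENE0020	3	43	stop_bounded	3	43	ATTGACGGCCTAACAAAGAGTTTATGGCCGACCAGCCCTCCGTACGTCTGCGATCCCGTCCCCACTGGTACATGGGTATTATTTCGACATCCTGTCGAACCGGTCTTCAGCAAAAAAGCCCACGTAGTA
TX0021	GENE0021	4	112	stop_bounded	190	50	CAACCTTATCGGTCCTTGTTGAAGTACACCATAGGTCTTATCGGTCAACCTCCATGTGGGCGGCGATTGTCAAGCTCTCGTATTTGGCCATTCACTCGCTGCGTCGAAAGGTTCCGACCAGAAGAAGTGCAATCATATCTGTTCGAAGAG
TX0022	GENE0022	3	39	stop_bounded	3	39	CCTGGAAGGGCGAATCGTACGTTCGAGCTCTCCAGCAATAGCATTGGCAAGCTAGAACCTCTGGGAAGCGTACGTGCTAAAGACGCAATCGTGCATTATACCGACGCCGTAACAGCG
TX0025	GENE0025	5	66	stop_bounded	53	50	GTAGGAGTGGGTCGGCGTGCAAGGGAAGATGAAATAGTTGAACCGAGGACGGCGTCCCCAGTAGGGCTTAGGCCATTGCCGACAATTCTACATCAGAGTCCAAAACTCCACCCGGGCACCTTCCCGTCACCAATATCCACCCAGAGCAGC
TX0027	GENE0027	3	63	stop_bounded	42	50	CTGAGTGAGTTATGCATAACGGTTCATACCTCTCATCGCTATGACTCAGTAAGGGCAGAGCGTCACCTACAGGTGGTCGCGCCATGGGGTGTTCTATTCCGCTGTGCTGAAGGACCGGTATCGGCCATTGCATTTAGATGCGGCCATCCA
TX0028	GENE0028	4	25	stop_bounded	4	25	GGATACACCAGGGGACGGTCCCCAGACAATTCGGCATATCTTAGTCTCAGGTCCCGATACCTGATATTCAAATTT
TX0029	GENE0029	5	52	stop_bounded	11	50	GGGCTAGCCTGTCATGCCCCAAGAGACAGCGGAGGTTCGAGCGCTTTGGCAGATGTTCCTGAGTGTATTTTTATACGTTTATCTCTAGGGGTAAACTCAAATGGCGCACTCGCCCGGTCTACCGCGACGAATACAGTCCGTGCAGGGATC
TX0030	GENE0030	4	73	stop_bounded	73	50	GCTAGTAAGGCGTCGCACAAGCACTGGAATAGGAGTAAATATGAGCCGCCGTTATTCTGCAAACGTAATGCTTGTCTTGCACGAAGCGAGTATCCGTGGTATTGTCTTATAAGGCTGTTCTTAGCTGACCGTACACAACCGGTTCGCACC
TX0031	GENE0031	5	46	stop_bounded	5	46	GAGTATGATAACAATTCAATTTGTTCCGTGTACTCAAAGGAAGCCAAAGACGCAAGGATTAGCTCAATTTGGGTGGCCCTGGGGAGCGAGCTTTCTGCCCGCGCATATGCTTTTCGTATACCGAAGTTCGTATTTCGT
TX0032	GENE0032	5	31	stop_bounded	5	31	GGTACCCGTCTTAAACGCACGAGTCTTGACGTTGCTTGGGTCATCGAGTCTTGCTTGCGGTGCCCCCGCCCCGAAGCGACCACATGGCCTGTC
TX0033	GENE0033	5	107	stop_bounded	176	50	GACGCTCAAGCATTATGTCCCAACACCGTTACATCGTGTTACCGAGTCACTCTACCCTATCAGCCAAGTGCTGATGGTAACTGGGTACCACTACGAGCTTCGTTGCAGAGAGCCAATGTAACCGCGCGTTATAGCGTTCAAACTGGCAGG
TX0034	GENE0034	4	94	stop_bounded	136	50	AATTCGCATGAACACGAAGCCAGTGTCCCGACCGAAACCCATGTACAGGTGGCCGCGGTAGTGTGGAGCAAGACAGTATCCCTTGGACGGTATAAATACCGAATCGGGGAAGTGGCCCTGGTGACCAATATTCAAGAGTGGAGACGTATT
TX0036	GENE0036	4	82	stop_bounded	100	50	ACAACTTGCGAAAGTTTCGGACACGTAAACTCTGCTGACAATTGCGTTAAAGTTGTCTTCACTGCAGTTATTGCGTATTGGTCCTACAGTTGCTGCCACGATGACGTTCTCATCAAACGTATTCGATGTTGGGGAATCTTAGGTGTTGGG
TX0037	GENE0037	3	97	stop_bounded	144	50	TCTCCTACCAGACAGATTAGGAAGCAACCTGCTAGGTGCTCTGCGATCAAGGAAATCAATAGAACAAGACCAGACGTGAAGAAAAAGAGTTATGGCTTGGATGCTTACTGGACAGCTGTCACGCGTGCAGAGGAAACGTGCTTATATGCC
TX0038	GENE0038	3	47	stop_bounded	3	47	GAGGGTGGTAGGGGCCTACGGCACTCGACGAGATCCTTTAGTGACCGTGTTGGTTCGTCACAACCCGAACCTGATGCGTGGAAAGTCAAACGGGACATCTTCACTTTTTTGCTTTCTGTGGCTCTACGCTTCCGAGCCCTC
TX0039	GENE0039	5	33	stop_bounded	5	33	TACAAACTAAACAGGGATCTTGCAAGTAGGGTCCATACAATTGTGCAATTTTCCACTTGGAAGCAGATAAGCCAGTTGACGAACGATAGCGTGCTCATT
TX0040	GENE0040	5	29	stop_bounded	5	29	GAAAGTCTCGCATCGACAGCCTCAGGTAACACGGATGCGAGTGGCCGGAAGGGCTACACAGCGAAATTTGTCGCAAAGAGGCCAAAA
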