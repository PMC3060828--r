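set	fwd_seq	fwd_start	fwd_len	fwd_gc	fwd_tm	rev_seq	rev_start	rev_len	rev_gc	rev_tm	product_len
1	ATTTAGCCAATGACACCTAGCC	193	22	45.5	58.2	CGATTTGCACGAGTATTTTCTC	1058	22	40.9	57.3	887
2	GTAACATGGTAAGTGTACCGGAAG	976	24	45.8	57.9	CGAGTTCCTTCTTTCCTTTTTAGTC	1956	25	40.0	59.9	1005
3	TGCATACGTGTACGTCGGAAC	1816	21	52.4	59.4	AGATAGAAACTGACCTGGATTGC	2619	23	43.5	57.3	826
4	TGGATCAGGACATCCTAATGGTG	2531	23	47.8	61.3	GTTTCGGCCAGGGTGGAAAT	3426	20	55.0	63.4	915
5	TTCAAAATATGCCCTCATCGG	3239	21	42.9	60.2	AAGTATTTGGCCGTTGCTTCTAC	4278	23	43.5	60.1	1062
6	CTAGGAACCACAATCACATTCG	4164	22	45.5	57.4	GCAAGTTTTAGTTCAGGGTCTG	5229	22	45.5	56.4	1087
7	TACCTCCGCCTCTCATACGC	4995	20	60.0	60.2	CATATTGTTCATTCGAGGGAAGG	5842	23	43.5	60.6	870
8	CATCCTACCTGTGGCAATCACAC	5555	23	52.2	61.8	CATCATGGCTCAGACCATGCC	6378	21	57.1	63.3	844
9	CCTCTCACTTCCTGTCCTTG	6152	20	55.0	54.2	AGCTGTGTAATAGCTTGCTTTAC	7200	23	39.1	54.0	1071
10	AGAAAGGAAGGAATCGAACCC	7118	21	47.6	59.2	TAGTGCCATCGTCAGGATCAG	8182	21	52.4	58.3	1085
11	GAATGGTGGCTCCCAATCAC	8006	20	55.0	59.7	TTGATGTGCCATTAGACGTTTTC	8866	23	39.1	59.7	883
12	CTAATCGCAACAGCCGTTTTC	8713	21	47.6	60.3	AGACCCGGTGATTGGAAGTCAC	9689	22	54.6	62.6	998
13	CCACTTTGGCTTTGAAGCAG	9569	20	50.0	58.5	TGGGTTGAGATGTGTTCATCC	10590	21	47.6	57.7	1042
14	ACCGCCTAAAAAACCTAAACC	10418	21	42.9	57.7	TTGGGAGAGGATTCCTGCTAC	11352	21	52.4	58.4	955
15	CTTTCACCTCCACATCATATGC	11011	22	45.5	57.2	GGATTTGCACCAAGAGTTTTTG	12029	22	40.9	59.3	1040
16	AAGACGCTAGGTTGTGATTCTAG	11857	23	43.5	55.6	CATGTTGTGAGGGCTGTCTG	12890	20	55.0	56.6	1053
17	CTACTTCACTCAAGCACTATGGTTG	12815	25	44.0	58.3	GTTAAATTGTTTGGCTGTTAGTGATG	13593	26	34.6	59.9	804
18	TCCCATTAAAAATCCCAGTC	13497	20	40.0	54.3	TTCGGAGACTTGCCATTAATAG	14487	22	40.9	57.0	1012
19	ACGGATTAGAAGCAACCCCAAT	14349	22	45.5	61.9	ATAAGGAGGGCTGCAAATCCTAG	15181	23	47.8	61.3	855
20	AAATATCCTTCTGAGGTGCAACC	14903	23	43.5	59.5	GAGCTAGAGGTGGAGGTTAAAATC	15717	24	45.8	58.2	838
21	GCTTAATATAAAGCACCGGTCTTG	15644	24	41.7	60.0	CTTCAGTGTTATGCTTTTGTTAAGC	9	25	36.0	58.2	1092
22	ACTTGAGTTTCCCCCCTACCC	16470	21	57.1	61.0	TCCTTTGGGTTTTAAGCTTACGCT	567	24	41.67	63.27	823
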