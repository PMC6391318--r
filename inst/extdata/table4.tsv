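lineage	family	TAT_223	GT_199	ATA_194	AC_21	AAAC	GT	AC_190	AAAC_annot
A	Fam 10	10	20	10	13	7	16	15	.
A	Fam 44	10	20	10	13	7	16	15	.
A	Fam 34	11	20	10	13	7	15	15	.
A	Fam 1	10	20	10	13	7	20	18	.
A	Fam 8	10	22	10	13	7	16	15	.
A	Fam 5	10	26	10	13	7	16	15	.
A	Fam 11	10	24	10	12	7	14	18	.
A	Fam 24	14	22	10	12	8	20	15	.
A	Fam 29	16	22	10	13	7	20	15	.
A	Fam 47	16	24	10	14	5	20	16	.
B	Fam 41	10	22	10	12	7	20	16	.
B	Fam 23	10	22	10	13	7	20	16	.
B	Fam 16	10	21	11	13	7	20	16	.
B	Fam 4	11	24	10	12	7	20	15	.
B	Fam 49	10	22	10	12	7	16	16	.
B	Fam 25	10	22	10	14	7	16	16	.
B	Fam 40	10	22	9	12	7	17	19	.
B	Fam 30	10	22	9	12	7	20	16	.
B	Fam 37	10	22	9	12	8	20	16	.
B	Fam 45	10	20	9	12	7	20	16	.
B	Fam 35	15	22	8	12	7	20	16	.
B	Fam 48	16	22	9	12	6	20	15	.
D	Fam 1	10	20	10	13	7	16	15	.
D	Fam 7	10	20	10	13	7	16	15	.
D	Fam 38	10	20	10	13	7	16	15	.
D	Fam 50	11	19	12	13	7	15	15	.
D	Fam 19	13	22	9	13	7	16	15	.
D	Fam 3	16	23	10	13	7	16	15	.
D	Fam 9	17	21	10	13	7	17	15	.
D	Fam 26	16	21	10	13	7	20	15	.
G	Fam 13	10	22	9	12	7	20	16	.
G	Fam 43	10	22	8	12	7	20	16	.
G	Fam 22	10	22	9	12	7	20	15	.
G	Fam 33	10	22	9	15	7	19	16	5
G	Fam 17	10	22	9	14	8	16	16	.
G	Fam 6	12	22	10	12	7	20	16	.
G	Fam 32	16	22	9	12	7	20	16	.
G	Fam 46	16	21	10	12	7	20	15	.
G	Fam 27	10	22	9	12	5	20	16	.
G	Fam 36	10	22	10	12	5	20	15	.
G	Fam 42	11	22	11	12	5	20	20	.
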