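marker_id	rs_id	kind	offset_kb	domain
TAT_223	.	STR	-223	1-99
GT_199	.	STR	-199	1-99
ATA_194	.	STR	-194	1-99
AC_21	.	STR	-21	1-99
AAAC	.	STR	-10	1-99
GT	.	STR	-5	1-99
IVS6-30G>T	rs12590497	SNP	-3.0	G,T
GTT527/GTC527	rs16999141	SNP	-2.6	T,C
IVS8-86T>G	rs10146519	SNP	-2.2	T,G
A669TG/G669TG	rs1048755	SNP	-1.0	A,G
C/T.124	rs12586535	SNP	-0.826	C,T
T/C.248	rs12586471	SNP	-0.702	T,C
A/G.485	rs56268847	SNP	-0.465	A,G
G/A.868	rs10467858	SNP	-0.082	G,A
C/G.910	rs10467857	SNP	-0.04	C,G
T/C.921	rs10467856	SNP	-0.029	T,C
C987GG/G987GG	rs12895357	SNP	0.987	C,G
TAA1118/TAC1118	rs7158733	SNP	1.118	A,C
C1178/A1178	rs3092822	SNP	1.178	C,A
C/T.ds1	rs77086230	SNP	1.5	C,T
C/T.ds2	rs79316375	SNP	2.0	C,T
G/A.3738	rs8004149	SNP	3.738	G,A
G/A.3770	rs111735934	SNP	3.77	G,A
C/T.3874	rs181752420	SNP	3.874	C,T
A/G.3912	rs7142326	SNP	3.912	A,G
C/T.3980	rs74071847	SNP	3.98	C,T
AC_190	.	STR	190	1-99
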