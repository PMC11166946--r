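mouse_symbol	mouse_id	human_symbol	human_id
Ace	ENSMUSG00000020681	ACE	ENSG00000159640
Ace2	ENSMUSG00000015405	ACE2	ENSG00000130234
Actn3	ENSMUSG00000006457	ACTN3	ENSG00000248746
Adh4	ENSMUSG00000037797	ADH4	ENSG00000198099
Agt	ENSMUSG00000031980	AGT	ENSG00000135744
Ahcyl	ENSMUSG00000048087	AHCY	ENSG00000101444
Akt1	ENSMUSG00000001729	AKT1	ENSG00000142208
Arg2	ENSMUSG00000021125	ARG2	ENSG00000081181
Atxn2	ENSMUSG00000042605	ATXN2	ENSG00000204842
B2m	ENSMUSG00000060802	B2M	ENSG00000166710
Bcl2l1	ENSMUSG00000007659	BCL2L1	ENSG00000171552
Bdnf	ENSMUSG00000048482	BDNF	ENSG00000176697
Calr	ENSMUSG00000003814	CALR	ENSG00000179218
Calu	ENSMUSG00000029767	CALU	ENSG00000128595
Capn11	ENSMUSG00000058626	CAPN11	ENSG00000137225
Ccl11	ENSMUSG00000020676	CCL11	ENSG00000172156
Gpr1	ENSMUSG00000046856	CMKLR2	ENSG00000183671
Cntf	ENSMUSG00000079415	CNTF	ENSG00000242689
Crp	ENSMUSG00000037942	CRP	ENSG00000132693
Cx3cl1	ENSMUSG00000031778	CX3CL1	ENSG00000006210
Cxcl10	ENSMUSG00000034855	CXCL10	ENSG00000169245
Cxcl12	ENSMUSG00000061353	CXCL12	ENSG00000107562
Cyp27b1	ENSMUSG00000006724	CYP27B1	ENSG00000111012
Egln3	ENSMUSG00000035105	EGLN3	ENSG00000129521
Epas1	ENSMUSG00000024140	EPAS1	ENSG00000116016
Fas	ENSMUSG00000024778	FAS	ENSG00000026103
Fasl	ENSMUSG00000000817	FASLG	ENSG00000117560
Fgf21	ENSMUSG00000030827	FGF21	ENSG00000105550
Fgf23	ENSMUSG00000000182	FGF23	ENSG00000118972
Fndc5	ENSMUSG00000001334	FNDC5	ENSG00000160097
Frem2	ENSMUSG00000037016	FREM2	ENSG00000150893
Gdf15	ENSMUSG00000038508	GDF15	ENSG00000130513
Hif1a	ENSMUSG00000021109	HIF1A	ENSG00000100644
Hif3a	ENSMUSG00000004328	HIF3A	ENSG00000124440
Hmox2	ENSMUSG00000004070	HMOX2	ENSG00000103415
Ifng	ENSMUSG00000055170	IFNG	ENSG00000111537
Igfbp6	ENSMUSG00000023046	IGFBP6	ENSG00000167779
Il10	ENSMUSG00000016529	IL10	ENSG00000136634
Il17a	ENSMUSG00000025929	IL17A	ENSG00000112115
Il4	ENSMUSG00000000869	IL4	ENSG00000113520
Il6	ENSMUSG00000025746	IL6	ENSG00000136244
Il7	ENSMUSG00000040329	IL7	ENSG00000104432
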