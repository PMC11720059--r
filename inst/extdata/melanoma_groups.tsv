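event	responder_phbr	responder_best_peptide	responder_best_hla	nonresponder_phbr	gene_symbol	premature_stop_in_nr	highlighted
chr1:84563245-84563256	0.04	YYNYKVRLF	HLA-C07:51	0.04	CTBS	FALSE	FALSE
chr4:4237071-4237077	0.05	HPILRSAAL	HLA-B35:03	0.06	TMEM128	FALSE	FALSE
chr7:75881487-75881490	0.3	LPSEVVYRL	HLA-B35:01	0.4	RHBDD2	FALSE	FALSE
chr5:74700753-74700851	0.44	SLQPPPLRFK	HLA-A03:01	1.57	HEXB	FALSE	TRUE
chr20:6006807-6006834	0.47	IKYENPWTI	HLA-C06:02	0.49	CRLS1	FALSE	FALSE
chr2:37317807-37317899	0.56	RTWIGEIPY	HLA-A32:01	1.99	PRKD3	FALSE	FALSE
chr2:11450008-11450011	0.58	VPAPREVGL	HLA-B07:02	2.18	E2F6	FALSE	TRUE
chr1:112669896-112669918	1	NEYQGTQAY	HLA-B44:03	0.77	CAPZA1	FALSE	FALSE
chr22:50204986-50205024	1.03	RQILGDPTY	HLA-B15:01	9.15	SELENOO	FALSE	TRUE
chr7:72901070-72901128	1.09	NPPTTVSQI	HLA-B51:01	0.69	POM121	FALSE	FALSE
chr1:236207133-236207172	1.17	STEEKLGEY	HLA-A01:01	0.96	GPR137B	FALSE	FALSE
chr22:31176262-31176358	1.17	SPVSDSQLL	HLA-B35:03	0.75	RNF185	FALSE	FALSE
chr9:33338507-33338509	1.24	SLKSEADATF	HLA-B15:01	1.72	NFX1	FALSE	FALSE
chr2:144229849-144229871	1.3	LFYRGSLYL	HLA-A23:01	9.09	GTDC1	FALSE	TRUE
chr11:86318936-86318960	1.35	GLKSETGSY	HLA-B15:01	0.89	HIKESHI	FALSE	FALSE
chr22:43074660-43074673	1.67	QSLPMLPRL	HLA-B57:01	NA	TTLL1	TRUE	FALSE
chr2:39254521-39254545	1.68	IESIVIELF	HLA-B44:02	0.79	MAP4K3	FALSE	FALSE
chr10:91997080-91997108	1.73	KRWMKIKSV	HLA-C06:02	1.14	BTAF1	FALSE	FALSE
chr7:6257736-6257769	1.82	AAVPEDLSL	HLA-C03:04	1.19	CYTH3	FALSE	FALSE
chr8:97696204-97696221	1.85	SIFSGIAAW	HLA-A32:01	3.12	MTDH	FALSE	TRUE
chr5:17143578-17143591	2.27	EEANTCSFW	HLA-B44:02	2.53	BASP1	FALSE	FALSE
chr13:95816081-95816104	2.34	KIQALQEAW	HLA-A32:01	2.6	UGGT2	FALSE	FALSE
chr6:35352929-35353001	2.58	NTKRRDSL	HLA-B08:01	6.43	PPARD	FALSE	FALSE
chr20:62843780-62843793	3.2	RFRETESGLEF	HLA-A24:02	5.25	TCFL5	FALSE	FALSE
chr3:47940517-47940534	3.39	GSDTTGESKSL	HLA-C08:02	3.41	MAP4	FALSE	FALSE
chr6:96897659-96897665	3.7	REQISRECL	HLA-B40:01	2.24	NDUFAF4	FALSE	FALSE
chr7:104740892-104740916	4.95	SRDQLGNMV	HLA-B39:01	1.72	LHFPL3	FALSE	FALSE
chr1:185091565-185091578	5.31	QEAITDGLEI	HLA-B40:01	9.98	RNF2	FALSE	FALSE
chr7:150408642-150408664	23.61	ELKETWRGHF	HLA-B08:01	35.71	LOC728743	FALSE	FALSE
chr20:348046-348063	30.87	RGSGELEGR	HLA-A31:01	24.59	NRSN2	FALSE	FALSE
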