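trial	arm	lar_yes	lar_no	nonlar_yes	nonlar_no	printed_or	printed_consistent
GSE106977	A	2	13	34	39	5.68	FALSE
GSE106977	B	1	6	9	15	3.60	TRUE
GSE25055	-	4	17	34	59	2.45	TRUE
GSE25065	-	1	8	18	27	2.52	FALSE
GSE32646	-	2	4	8	12	1.33	TRUE
BrighTNess	A	15	25	112	85	2.20	TRUE
BrighTNess	B	10	12	59	41	1.73	TRUE
BrighTNess	C	4	18	36	65	2.49	TRUE
CALGB40603	1	6	6	20	32	0.63	TRUE
CALGB40603	2	5	8	20	21	1.52	TRUE
CALGB40603	3	6	6	23	23	1.00	TRUE
CALGB40603	4	5	7	38	15	3.55	TRUE
BEAUTY	-	2	7	21	12	6.13	TRUE
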