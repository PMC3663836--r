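case_id	sex	age	location	genotype	mutation	fish_14q	sdhb_ihc	followup	risk	histology	carney_triad
1	F	58	Stomach	KIT ex 11	Y553_W557del	Loss	NA	DOD	H	S	FALSE
2	F	37	Stomach	PDGFRA ex 18	D842V	Loss	NA	WD	L	S	FALSE
3	M	55	Stomach	PDGFRA ex 14	N659K	Loss	NA	WD	L	E	FALSE
4	F	73	Stomach	PDGFRA ex 18	D842V	Loss	NA	WD	L	E	FALSE
5	F	54	Stomach	KIT ex 11	M552_W557del	Loss	NA	WD	I	S&E	FALSE
6	M	44	Stomach	KIT ex 11	W557R	Loss	NA	WD	I	S&E	FALSE
7	F	78	Stomach	KIT ex 11	P551_E561delinsLQ	Diploid	NA	AWD	H	S	FALSE
8	F	65	Stomach	KIT ex 11	W557_V560delinsF	Loss	NA	AWD	H	E	FALSE
9	M	85	Stomach	KIT ex 11	V559A	Loss	NA	WD	L	S&E	FALSE
10	M	62	Stomach	PDGFRA ex 18	D842V	Loss	NA	WD	H	E	FALSE
11	M	44	Stomach	PDGFRA ex 18	D842V	Loss	NA	WD	I	S	FALSE
12	M	70	Stomach	KIT ex 11	W557_K558del	Loss	NA	AWD	H	E	FALSE
13	M	77	Stomach	KIT ex 11	V559D	Loss	NA	WD	L	E&S	FALSE
14	F	27	Stomach	KIT ex 11	556_573del	Loss	NA	AWD	I	S	FALSE
15	M	71	Stomach	KIT ex 11	V560_G565del	Loss	NA	AWD	H	S	FALSE
16	M	72	Stomach	PDGFRA ex 18	D842_M844del	Loss	NA	WD	I	E	FALSE
17	M	72	Stomach	KIT ex 11	K558_V559delinsN	Loss	NA	AWD	H	S	FALSE
18	M	62	Stomach	KIT ex 11	V554D	Loss	NA	WD	I	S	FALSE
19	M	67	Stomach	KIT ex 11	W557_K558del	Diploid	NA	DOD	H	S	FALSE
20	M	69	Stomach	PDGFRA ex 18	D842_I843del	Loss	NA	WD	I	S	FALSE
21	M	74	Stomach	KIT ex 11	V560D	Loss	NA	DOD	H	E	FALSE
22	F	48	Stomach	KIT ex 11	K550_V555del	Loss	NA	WD	H	S	FALSE
23	M	49	Stomach	PDGFRA ex 18	D842V	Trisomy	NA	WD	H	E	FALSE
24	M	68	Stomach	PDGFRA ex 12	V561D	Loss	NA	WD	I	E&S	FALSE
25	M	50	Stomach	PDGFRA ex 18	D842V	Loss	NA	WD	L	E	FALSE
26	F	71	Stomach	KIT ex 11	W557_K558del	Loss	NA	AWD	H	E	FALSE
27	F	46	Stomach	PDGFRA ex 18	D842V	Diploid	NA	WD	I	E	FALSE
50	F	58	Stomach	KIT ex 9	S476I	NA	positive	NA	NA	E&S	FALSE
51	F	22	Stomach	KIT ex 11	Y553_W557del	NA	positive	NA	NA	E	FALSE
52	M	58	Stomach	BRAF ex 15	V600E	Diploid	positive	NA	NA	E&S	FALSE
28	F	24	Stomach	WT	WT	NA	NA	NA	NA	E	FALSE
29	F	22	Stomach	WT	WT	NA	NA	NA	NA	E	FALSE
30	F	20	Stomach	WT	WT	NA	NA	NA	NA	E	FALSE
32	F	22	Stomach	WT	WT	NA	NA	NA	NA	E	FALSE
35	F	23	Stomach	WT	WT	NA	negative	NA	NA	E	FALSE
36	F	21	Stomach	WT	WT	Diploid	negative	NA	NA	E	FALSE
38	F	25	Stomach	WT	WT	Diploid	negative	NA	NA	E	FALSE
46	M	22	Stomach	WT	WT	NA	negative	NA	NA	E	FALSE
48	M	20	Stomach	WT	WT	NA	negative	NA	NA	E	FALSE
49	F	46	Stomach	WT	WT	NA	negative	NA	NA	NA	FALSE
53	F	20	Jejunum	WT	WT	Diploid	positive	NA	NA	E&S	FALSE
54	F	78	Stomach	WT	WT	NA	NA	NA	NA	E	FALSE
55	F	50	Stomach	WT	WT	NA	NA	NA	NA	E	FALSE
56	M	42	Stomach	WT	WT	NA	NA	NA	NA	S	FALSE
60	F	33	Stomach	WT	WT	NA	positive	NA	NA	S	FALSE
63	F	30	Jejunum	WT	WT	Diploid	positive	NA	NA	S	FALSE
64	F	40	Stomach	WT	WT	NA	negative	NA	NA	E	FALSE
65	F	28	Stomach	WT	WT	NA	negative	NA	NA	E	TRUE
66	F	54	Ileum	WT	WT	Diploid	positive	NA	NA	S	FALSE
68	F	55	Stomach	WT	WT	NA	negative	NA	NA	E	FALSE
69	F	49	Stomach	WT	WT	NA	negative	NA	NA	E	FALSE
70	F	31	Stomach	WT	WT	NA	negative	NA	NA	E	FALSE
71	M	45	Ileum	WT	WT	Trisomy	positive	NA	NA	E	FALSE
72	F	46	Stomach	WT	WT	NA	positive	NA	NA	S	FALSE
73	M	37	Retroperitoneum	WT	WT	Diploid	positive	NA	NA	S	FALSE
31	F	15	Stomach	WT	WT	NA	NA	NA	NA	E	FALSE
33	M	13	Stomach	WT	WT	NA	NA	NA	NA	E	FALSE
34	F	14	Stomach	WT	WT	NA	NA	NA	NA	E	FALSE
37	M	14	Stomach	WT	WT	Diploid	negative	NA	NA	S&E	FALSE
39	F	10	Stomach	WT	WT	Diploid	negative	NA	NA	S&E	FALSE
40	F	17	Stomach	WT	WT	Diploid	negative	NA	NA	E	FALSE
41	M	14	Stomach	WT	WT	Diploid	negative	NA	NA	E	TRUE
42	F	17	Stomach	WT	WT	Diploid	negative	NA	NA	E	TRUE
43	F	10	Stomach	WT	WT	NA	NA	NA	NA	E	FALSE
44	F	16	Stomach	WT	WT	NA	NA	NA	NA	E	TRUE
45	F	8	Stomach	WT	WT	NA	negative	NA	NA	E	FALSE
47	M	18	Stomach	WT	WT	NA	negative	NA	NA	E	FALSE
57	M	10	Stomach	WT	WT	NA	negative	NA	NA	E	FALSE
58	F	12	Stomach	WT	WT	NA	NA	NA	NA	NA	FALSE
59	F	11	Stomach	WT	WT	NA	negative	NA	NA	E	FALSE
61	M	18	Stomach	WT	WT	NA	NA	NA	NA	E	FALSE
62	F	19	Stomach	WT	WT	NA	negative	NA	NA	E	FALSE
67	F	18	Stomach	WT	WT	NA	negative	NA	NA	E	FALSE
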