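sample_id	group	location	unit_id	n_sequences	n_otus
Bux.P.A1	wild	Buxton	Bux.P.A	193	3
Bux.P.A2	wild	Buxton	Bux.P.A	329	4
Bux.P.A3	wild	Buxton	Bux.P.A	468	3
Bux.P.B1	wild	Buxton	Bux.P.B	787	8
Bux.P.B2	wild	Buxton	Bux.P.B	349	8
Bux.P.B3	wild	Buxton	Bux.P.B	59	2
Bux.P.C1	wild	Buxton	Bux.P.C	6	1
Bux.P.C2	wild	Buxton	Bux.P.C	0	0
Bux.P.C3	wild	Buxton	Bux.P.C	18	1
Bux.P.D1	wild	Buxton	Bux.P.D	3	1
Bux.P.D2	wild	Buxton	Bux.P.D	33	4
Bux.P.E1	wild	Buxton	Bux.P.E	9	1
Bux.P.E2	wild	Buxton	Bux.P.E	2	1
Bux.P.E3	wild	Buxton	Bux.P.E	628	2
Bux.P.F1	wild	Buxton	Bux.P.F	425	4
Bux.P.F2	wild	Buxton	Bux.P.F	852	3
Bux.P.F3	wild	Buxton	Bux.P.F	639	5
Bux.P.G1	wild	Buxton	Bux.P.G	190	9
Bux.P.G2	wild	Buxton	Bux.P.G	830	7
Bux.P.G3	wild	Buxton	Bux.P.G	61	5
Tum.P.A1	wild	Tumut	Tum.P.A	592	9
Tum.P.A2	wild	Tumut	Tum.P.A	121	4
Tum.P.A3	wild	Tumut	Tum.P.A	45	2
Tum.P.B1	wild	Tumut	Tum.P.B	322	4
Tum.P.B2	wild	Tumut	Tum.P.B	362	2
Tum.P.B3	wild	Tumut	Tum.P.B	371	2
Tum.P.C1	wild	Tumut	Tum.P.C	211	8
Tum.P.C2	wild	Tumut	Tum.P.C	50	4
Tum.P.C3	wild	Tumut	Tum.P.C	0	0
Tum.P.D1	wild	Tumut	Tum.P.D	528	3
Tum.P.D2	wild	Tumut	Tum.P.D	126	3
Tum.P.D3	wild	Tumut	Tum.P.D	949	13
Tum.P.E1	wild	Tumut	Tum.P.E	520	8
Tum.P.E2	wild	Tumut	Tum.P.E	178	7
Tum.P.E3	wild	Tumut	Tum.P.E	360	8
FFPF.Col.1	domesticated	EMAI_FFPF	FFPF.Col	86	3
FFPF.Col.2	domesticated	EMAI_FFPF	FFPF.Col	12	3
FFPF.Col.3	domesticated	EMAI_FFPF	FFPF.Col	15	2
FFPF.Col.4	domesticated	EMAI_FFPF	FFPF.Col	16	3
FFPF.Col.5	domesticated	EMAI_FFPF	FFPF.Col	12	1
FFPF.Col.6	domesticated	EMAI_FFPF	FFPF.Col	12	2
FFPF.Col.7	domesticated	EMAI_FFPF	FFPF.Col	57	2
FFPF.Col.8	domesticated	EMAI_FFPF	FFPF.Col	596	2
GPII.Col.1	domesticated	Gosford_PII	GPII.Col	557	2
GPII.Col.2	domesticated	Gosford_PII	GPII.Col	100	2
GPII.Col.3	domesticated	Gosford_PII	GPII.Col	143	4
GPII.Col.4	domesticated	Gosford_PII	GPII.Col	98	1
GPII.Col.5	domesticated	Gosford_PII	GPII.Col	21	1
GPII.Col.6	domesticated	Gosford_PII	GPII.Col	540	2
GPII.Col.7	domesticated	Gosford_PII	GPII.Col	21	1
GPII.Col.8	domesticated	Gosford_PII	GPII.Col	26	1
GPII.Col.9	domesticated	Gosford_PII	GPII.Col	262	3
MQ.Col.1	domesticated	Macquarie	MQ.Col	155	1
MQ.Col.2	domesticated	Macquarie	MQ.Col	243	1
MQ.Col.3	domesticated	Macquarie	MQ.Col	21	1
MQ.Col.4	domesticated	Macquarie	MQ.Col	76	3
MQ.Col.5	domesticated	Macquarie	MQ.Col	109	1
MQ.Col.6	domesticated	Macquarie	MQ.Col	837	3
PBS.1	control	blank	PBS	0	0
PBS.2	control	blank	PBS	2	1
PBS.3	control	blank	PBS	0	0
E.coli	control	positive	Ecoli	0	0
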