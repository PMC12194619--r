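subject	age_yr	body_mass_kg	stature_cm	bmi_kg_m2	sport	training_days_per_week
1	23	74	169	25.9	Mixed martial arts	3
2	23	71	176	22.9	Resistance training	2
3	21	66	170	22.8	Resistance training	3
4	28	70	181	21.4	Fencing	2
5	23	96	184	28.4	Resistance training	2
6	22	73	175	23.8	Futsal	5
7	19	94	195	24.7	Basketball	2
8	22	73	174	24.1	Soccer	4
9	21	73	177	23.3	Soccer	4
10	24	91	182	27.5	Basketball	3
11	23	74	172	25.0	Soccer	5
12	23	75	181	22.9	Resistance training	4
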