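case	age_of_diagnosis	hla	sex	mode_of_delivery	region	siblings	total_breastfeeding	gluten_introduction	control_pool_n
1	2	NA	Male	NA	North	No	1 to 3	4 to 7	177
2	3	DR3-DQ2.5/DR4-DQ8	Female	Cesarean	North	Yes	1 to 3	NA	230
3	3	DR3-DQ2.5/DR15-DQ602	Female	Vaginal	East	Yes	8 to 9	4 to 7	143
4	4	DR4-DQ8/DR7-DQ2.2	Male	Vaginal	East	Yes	4 to 7	4 to 7	143
5	4	DR4-DQ8/DR7-DQ2.2	Female	Cesarean	South	Yes	8 to 9	4 to 7	199
6	4	DR3-DQ2.5/DR5-DQ7	Female	Vaginal	East	Yes	4 to 7	4 to 7	143
7	5	DR3-DQ2.5/DR3-DQ2.5	Female	Vaginal	West	Yes	8 to 9	8 to 9	242
8	6	DR4-DQ8	Male	Vaginal	North	Yes	8 to 9	4 to 7	230
9	8	DR4-DQ8/DR4-DQ8	Female	Vaginal	West	No	8 to 9	8 to 9	156
10	9	DR3-DQ2.5/DR13-DQ604	Male	NA	North	NA	8 to 9	4 to 7	426
11	10	DR3-DQ2.5/DR9-DQ9	Female	Vaginal	South	Yes	1 to 3	4 to 7	199
12	11	DR3-DQ2	Male	Vaginal	West	Yes	1 to 3	4 to 7	242
13	12	DR5-DQ7/DR7-DQ2.5	Female	Vaginal	North	No	4 to 7	8 to 9	177
14	13	DR3-DQ2.5/DR15-DQ602	Female	Vaginal	South	Yes	1 to 3	4 to 7	199
15	13	DR4-DQ8/DR5-DQ7	Female	Vaginal	South	Yes	1 to 3	4 to 7	199
16	13	DR3-DQ2.5/DR15-DQ602	Female	Vaginal	East	No	4 to 7	8 to 9	95
17	14	NA	Female	Vaginal	East	Yes	8 to 9	4 to 7	143
18	14	DR3-DQ2.5/DR4-DQ8	Female	Vaginal	East	No	1 to 3	4 to 7	95
19	15	DR4-DQ8/DR15-DQ602	Male	Vaginal	South	Yes	8 to 9	4 to 7	199
20	15	DR4-DQ7/DR13-DQ603	Female	NA	North	No	8 to 9	4 to 7	177
21	16	DR3-DQ2.5/DR4-DQ8	Female	Vaginal	North	Yes	8 to 9	4 to 7	230
22	17	DR3-DQ2.5/DR8-DQ4	Male	Vaginal	North	No	8 to 9	8 to 9	177
23	17	DR3-DQ2.5/DR15-DQ602	Female	Vaginal	East	Yes	8 to 9	4 to 7	143
24	18	DR4-DQ8/DR13-DQ604	Female	Vaginal	West	Yes	8 to 9	4 to 7	242
25	19	DR4-DQ8/DR15-DQ602	Male	Vaginal	West	Yes	NA	NA	242
26	20	DR3-DQ2.5/DR7-DQ2.2	Male	Vaginal	North	Yes	8 to 9	4 to 7	230
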