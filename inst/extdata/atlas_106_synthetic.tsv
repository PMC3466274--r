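# dcgnet 0.1.0
# type: atlas
roi_id	roi_name	region	x	y	z
1	Subcortical_01	Subcortical	-52.5	-7.5	20
2	Subcortical_02	Subcortical	49.5	-6	29
3	Subcortical_03	Subcortical	-46.5	-4.5	18.5
4	Subcortical_04	Subcortical	43.5	-3	27.5
5	Subcortical_05	Subcortical	-40.5	-1.5	17
6	Subcortical_06	Subcortical	37.5	0	26
7	Subcortical_07	Subcortical	-54	1.5	15.5
8	Subcortical_08	Subcortical	51	3	24.5
9	Subcortical_09	Subcortical	-48	4.5	14
10	Subcortical_10	Subcortical	45	6	23
11	Parietal_01	Parietal	-43.9	24.8	6.2
12	Parietal_02	Parietal	40.9	26.3	15.2
13	Parietal_03	Parietal	-37.9	27.8	4.7
14	Parietal_04	Parietal	34.9	29.3	13.7
15	Parietal_05	Parietal	-31.9	30.8	3.2
16	Parietal_06	Parietal	28.9	32.3	12.2
17	Parietal_07	Parietal	-45.4	33.8	1.7
18	Parietal_08	Parietal	42.4	35.3	10.7
19	Parietal_09	Parietal	-39.4	36.8	0.2
20	Parietal_10	Parietal	36.4	38.3	9.2
21	Occipital_01	Occipital	-21.4	44.8	-16.2
22	Occipital_02	Occipital	18.4	46.3	-7.2
23	Occipital_03	Occipital	-15.4	47.8	-17.7
24	Occipital_04	Occipital	12.4	49.3	-8.7
25	Occipital_05	Occipital	-9.4	50.8	-19.2
26	Occipital_06	Occipital	6.4	52.3	-10.2
27	Occipital_07	Occipital	-22.9	53.8	-20.7
28	Occipital_08	Occipital	19.9	55.3	-11.7
29	Occipital_09	Occipital	-16.9	56.8	-22.2
30	Occipital_10	Occipital	13.9	58.3	-13.2
31	Occipital_11	Occipital	-10.9	59.8	-23.7
32	Occipital_12	Occipital	7.9	61.3	-14.7
33	Occipital_13	Occipital	-4.9	43.3	-25.2
34	Occipital_14	Occipital	21.4	44.8	-16.2
35	Cerebelum_01	Cerebelum	-6.4	44.8	-16.2
36	Cerebelum_02	Cerebelum	9.4	46.3	-7.2
37	Cerebelum_03	Cerebelum	-12.4	47.8	-17.7
38	Cerebelum_04	Cerebelum	15.4	49.3	-8.7
39	Cerebelum_05	Cerebelum	-18.4	50.8	-19.2
40	Cerebelum_06	Cerebelum	21.4	52.3	-10.2
41	Cerebelum_07	Cerebelum	-4.9	53.8	-20.7
42	Cerebelum_08	Cerebelum	7.9	55.3	-11.7
43	Cerebelum_09	Cerebelum	-10.9	56.8	-22.2
44	Cerebelum_10	Cerebelum	13.9	58.3	-13.2
45	Cerebelum_11	Cerebelum	-16.9	59.8	-23.7
46	Cerebelum_12	Cerebelum	19.9	61.3	-14.7
47	Cerebelum_13	Cerebelum	-22.9	43.3	-25.2
48	Cerebelum_14	Cerebelum	6.4	44.8	-16.2
49	Cerebelum_15	Cerebelum	-9.4	46.3	-7.2
50	Cerebelum_16	Cerebelum	12.4	47.8	-17.7
51	Cerebelum_17	Cerebelum	-15.4	49.3	-8.7
52	Cerebelum_18	Cerebelum	18.4	50.8	-19.2
53	Cerebelum_19	Cerebelum	-21.4	52.3	-10.2
54	Cerebelum_20	Cerebelum	4.9	53.8	-20.7
55	Frontal_01	Frontal	-28.9	24.8	6.2
56	Frontal_02	Frontal	31.9	26.3	15.2
57	Frontal_03	Frontal	-34.9	27.8	4.7
58	Frontal_04	Frontal	37.9	29.3	13.7
59	Frontal_05	Frontal	-40.9	30.8	3.2
60	Frontal_06	Frontal	43.9	32.3	12.2
61	Frontal_07	Frontal	-27.4	33.8	1.7
62	Frontal_08	Frontal	30.4	35.3	10.7
63	Frontal_09	Frontal	-33.4	36.8	0.2
64	Frontal_10	Frontal	36.4	38.3	9.2
65	Frontal_11	Frontal	-39.4	39.8	-1.3
66	Frontal_12	Frontal	42.4	41.3	7.7
67	Frontal_13	Frontal	-45.4	23.3	-2.8
68	Frontal_14	Frontal	28.9	24.8	6.2
69	Frontal_15	Frontal	-31.9	26.3	15.2
70	Frontal_16	Frontal	34.9	27.8	4.7
71	Frontal_17	Frontal	-37.9	29.3	13.7
72	Frontal_18	Frontal	40.9	30.8	3.2
73	Frontal_19	Frontal	-43.9	32.3	12.2
74	Frontal_20	Frontal	27.4	33.8	1.7
75	Frontal_21	Frontal	-30.4	35.3	10.7
76	Frontal_22	Frontal	33.4	36.8	0.2
77	Temporal_01	Temporal	-37.5	-7.5	20
78	Temporal_02	Temporal	40.5	-6	29
79	Temporal_03	Temporal	-43.5	-4.5	18.5
80	Temporal_04	Temporal	46.5	-3	27.5
81	Temporal_05	Temporal	-49.5	-1.5	17
82	Temporal_06	Temporal	52.5	0	26
83	Temporal_07	Temporal	-36	1.5	15.5
84	Temporal_08	Temporal	39	3	24.5
85	Limbic_01	Limbic	-28.9	-39.8	6.2
86	Limbic_02	Limbic	31.9	-38.3	15.2
87	Limbic_03	Limbic	-34.9	-36.8	4.7
88	Limbic_04	Limbic	37.9	-35.3	13.7
89	Limbic_05	Limbic	-40.9	-33.8	3.2
90	Limbic_06	Limbic	43.9	-32.3	12.2
91	Limbic_07	Limbic	-27.4	-30.8	1.7
92	Limbic_08	Limbic	30.4	-29.3	10.7
93	Insular_01	Insular	-6.4	-59.8	-16.2
94	Insular_02	Insular	9.4	-58.3	-7.2
95	Central_01	Central	-21.4	-59.8	-16.2
96	Central_02	Central	18.4	-58.3	-7.2
97	Central_03	Central	-15.4	-56.8	-17.7
98	Central_04	Central	12.4	-55.3	-8.7
99	Central_05	Central	-9.4	-53.8	-19.2
100	Central_06	Central	6.4	-52.3	-10.2
101	Cingulum_01	Cingulum	-43.9	-39.8	6.2
102	Cingulum_02	Cingulum	40.9	-38.3	15.2
103	Cingulum_03	Cingulum	-37.9	-36.8	4.7
104	Cingulum_04	Cingulum	34.9	-35.3	13.7
105	Cingulum_05	Cingulum	-31.9	-33.8	3.2
106	Cingulum_06	Cingulum	28.9	-32.3	12.2
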