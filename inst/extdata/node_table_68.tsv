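region	hemisphere	x	y	z	radius_mm	peak_z	volume_mm3
Superior frontal gyrus (dorsal)	L	-10	66	26	5	6.46	5736
Superior frontal gyrus (medial)	L	0	68	2	5	6.54	9912
Superior frontal gyrus (medial)	R	4	64	0	5	6.35	3848
Orbitofrontal gyrus (superior)	L	-8	68	-8	5	5.7	416
Middle frontal gyrus	L	-30	28	46	5	5.84	3120
Orbitofrontal gyrus (middle)	L	-28	36	-14	5	5.95	440
Orbitofrontal gyrus (medial)	L	0	68	-4	5	7.37	5320
Orbitofrontal gyrus (medial)	R	4	64	-6	5	7.73	5760
Orbitofrontal gyrus (inferior)	L	-28	34	-14	5	5.7	1416
Rectus gyrus	L	-4	52	-16	5	6.35	1528
Rectus gyrus	R	4	42	-16	5	6.64	1208
Precentral gyrus	L	-56	-6	30	5	7.24	560
Precentral gyrus	R	36	-20	44	5	7.68	6552
Paracentral lobule	L	-12	-34	50	5	5.55	1072
Paracentral lobule	R	12	-40	52	5	6.39	3832
Supplementary motor area	R	44	51	67	5	5.85	1888
Postcentral gyrus	L	-54	-8	26	5	7.34	5232
Postcentral gyrus	R	54	-12	36	5	7.68	13464
Anterior cingulate gyrus	L	-2	38	-8	5	6.63	3016
Anterior cingulate gyrus	R	4	34	-6	5	6.01	960
Middle cingulate gyrus	L	-8	-44	48	5	7.95	5248
Middle cingulate gyrus	R	8	-42	50	5	6.32	6344
Posterior cingulate gyrus	L	-8	-48	32	5	7.16	2008
Superior parietal gyrus	L	-16	-56	52	5	6.15	1104
Superior parietal gyrus	R	16	-50	56	5	6.25	368
Inferior parietal gyrus	L	-36	-78	42	5	5.96	336
Precuneus	L	-10	-44	48	5	8.15	10472
Precuneus	R	2	-50	52	5	7.88	9160
Angular gyrus	L	-40	-74	40	5	6.32	3120
Supramarginal gyrus	L	-64	-32	32	5	5.02	1944
Supramarginal gyrus	R	48	-16	30	5	6.44	6336
Superior temporal gyrus	L	-58	-2	-14	5	5.62	8656
Superior temporal gyrus	R	62	-8	2	5	7.13	14152
Middle temporal gyrus	L	-58	-4	-18	5	7.34	9608
Middle temporal gyrus	R	58	-6	-14	5	5.8	5192
Inferior temporal gyrus	L	-54	-4	-28	5	6.46	2544
Inferior temporal gyrus	R	54	60	22	5	5.2	256
Temporal pole (superior)	L	-54	6	-16	5	4.98	1184
Temporal pole (superior)	R	62	2	0	5	5.78	2360
Temporal pole (middle)	L	-58	-4	-18	5	4.84	1336
Temporal pole (middle)	R	28	12	-36	5	5.33	2312
Heschl's gyrus	L	-34	-24	14	5	4.56	1288
Heschl's gyrus	R	36	-26	16	5	6.83	1976
Fusiform gyrus	L	-28	-50	-12	5	7.56	8240
Fusiform gyrus	R	24	-64	-8	5	7.72	7472
Superior occipital gyrus	L	-16	-94	20	5	8.38	7512
Superior occipital gyrus	R	18	-90	26	5	7.32	5624
Middle occipital gyrus	L	-18	-90	18	5	7.11	9472
Middle occipital gyrus	R	26	-88	20	5	8.32	5152
Lingual gyrus	L	-20	-66	-12	5	7.56	13360
Lingual gyrus	R	24	-52	-10	5	8.01	14136
Calcarine cortex	L	-10	-60	6	5	7.96	14440
Calcarine cortex	R	8	-90	12	5	7.73	12144
Cuneus	L	-8	-74	18	5	7.93	10704
Cuneus	R	10	-92	16	5	7.52	9000
Parahippocampal cortex	L	-12	-34	50	5	5.55	1784
Parahippocampal cortex	R	12	-40	52	5	6.39	3832
Insula	L	-36	-16	16	5	5.43	1432
Insula	R	34	-14	6	5	6.39	3832
Rolandic operculum	L	-38	-16	18	5	5.47	1912
Rolandic operculum	R	66	-6	8	5	6.91	7008
Putamen	R	34	-14	2	5	6.16	1372
Pallidum	R	28	-12	-2	5	5.37	248
Thalamus	L	-16	-26	0	5	5.01	504
Thalamus	R	16	-26	0	5	4.05	416
Amygdala	L	-20	-6	-18	5	3.64	144
Hippocampus	L	-22	-14	-24	5	5.25	208
Hippocampus	R	24	-12	-22	5	5.93	552
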