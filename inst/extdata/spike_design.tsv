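id	subgroup	ratio	conc_mix1	conc_mix2	molecules_mix1	molecules_mix2
SPK_001	A	4	0.1	0.025	0	0
SPK_002	A	4	0.144241725524107	0.0360604313810267	0	0
SPK_003	A	4	0.208056753821717	0.0520141884554293	0	0
SPK_004	A	4	0.300104651781887	0.0750261629454718	0	0
SPK_005	A	4	0.432876128108306	0.108219032027076	0	0
SPK_006	A	4	0.624387996565363	0.156096999141341	1	0
SPK_007	A	4	0.900628020211279	0.22515700505282	1	0
SPK_008	A	4	1.29908139690635	0.324770349226587	1	0
SPK_009	A	4	1.87381742286038	0.468454355715096	2	0
SPK_010	A	4	2.70282658390516	0.675706645976291	3	1
SPK_011	A	4	3.89860370254907	0.974650925637268	4	1
SPK_012	A	4	5.62341325190349	1.40585331297587	6	1
SPK_013	A	4	8.11130830789687	2.02782707697422	8	2
SPK_014	A	4	11.6998910658907	2.92497276647267	12	3
SPK_015	A	4	16.8761247578815	4.21903118947037	17	4
SPK_016	A	4	24.3424135523692	6.0856033880923	24	6
SPK_017	A	4	35.1119173421513	8.77797933553783	35	9
SPK_018	A	4	50.6460354389171	12.6615088597293	51	13
SPK_019	A	4	73.0527154266446	18.2631788566611	73	18
SPK_020	A	4	105.372497273607	26.3431243184018	105	26
SPK_021	A	4	151.991108295293	37.9977770738233	152	38
SPK_022	A	4	219.234597248345	54.8086493120862	219	55
SPK_023	A	4	316.227766016838	79.0569415042095	316	79
SPK_024	B	1	0.1	0.1	0	0
SPK_025	B	1	0.144241725524107	0.144241725524107	0	0
SPK_026	B	1	0.208056753821717	0.208056753821717	0	0
SPK_027	B	1	0.300104651781887	0.300104651781887	0	0
SPK_028	B	1	0.432876128108306	0.432876128108306	0	0
SPK_029	B	1	0.624387996565363	0.624387996565363	1	1
SPK_030	B	1	0.900628020211279	0.900628020211279	1	1
SPK_031	B	1	1.29908139690635	1.29908139690635	1	1
SPK_032	B	1	1.87381742286038	1.87381742286038	2	2
SPK_033	B	1	2.70282658390516	2.70282658390516	3	3
SPK_034	B	1	3.89860370254907	3.89860370254907	4	4
SPK_035	B	1	5.62341325190349	5.62341325190349	6	6
SPK_036	B	1	8.11130830789687	8.11130830789687	8	8
SPK_037	B	1	11.6998910658907	11.6998910658907	12	12
SPK_038	B	1	16.8761247578815	16.8761247578815	17	17
SPK_039	B	1	24.3424135523692	24.3424135523692	24	24
SPK_040	B	1	35.1119173421513	35.1119173421513	35	35
SPK_041	B	1	50.6460354389171	50.6460354389171	51	51
SPK_042	B	1	73.0527154266446	73.0527154266446	73	73
SPK_043	B	1	105.372497273607	105.372497273607	105	105
SPK_044	B	1	151.991108295293	151.991108295293	152	152
SPK_045	B	1	219.234597248345	219.234597248345	219	219
SPK_046	B	1	316.227766016838	316.227766016838	316	316
SPK_047	C	0.666666666666667	0.05	0.075	0	0
SPK_048	C	0.666666666666667	0.0721208627620533	0.10818129414308	0	0
SPK_049	C	0.666666666666667	0.104028376910859	0.156042565366288	0	0
SPK_050	C	0.666666666666667	0.150052325890944	0.225078488836416	0	0
SPK_051	C	0.666666666666667	0.216438064054153	0.324657096081229	0	0
SPK_052	C	0.666666666666667	0.312193998282681	0.468290997424022	0	0
SPK_053	C	0.666666666666667	0.450314010105639	0.675471015158459	0	1
SPK_054	C	0.666666666666667	0.649540698453174	0.974311047679761	1	1
SPK_055	C	0.666666666666667	0.936908711430192	1.40536306714529	1	1
SPK_056	C	0.666666666666667	1.35141329195258	2.02711993792887	1	2
SPK_057	C	0.666666666666667	1.94930185127454	2.9239527769118	2	3
SPK_058	C	0.666666666666667	2.81170662595175	4.21755993892762	3	4
SPK_059	C	0.666666666666667	4.05565415394844	6.08348123092265	4	6
SPK_060	C	0.666666666666667	5.84994553294533	8.774918299418	6	9
SPK_061	C	0.666666666666667	8.43806237894074	12.6570935684111	8	13
SPK_062	C	0.666666666666667	12.1712067761846	18.2568101642769	12	18
SPK_063	C	0.666666666666667	17.5559586710757	26.3339380066135	18	26
SPK_064	C	0.666666666666667	25.3230177194585	37.9845265791878	25	38
SPK_065	C	0.666666666666667	36.5263577133223	54.7895365699834	37	55
SPK_066	C	0.666666666666667	52.6862486368036	79.0293729552054	53	79
SPK_067	C	0.666666666666667	75.9955541476467	113.99333122147	76	114
SPK_068	C	0.666666666666667	109.617298624172	164.425947936258	110	164
SPK_069	C	0.666666666666667	158.113883008419	237.170824512628	158	237
SPK_070	D	0.5	0.05	0.1	0	0
SPK_071	D	0.5	0.0721208627620533	0.144241725524107	0	0
SPK_072	D	0.5	0.104028376910859	0.208056753821717	0	0
SPK_073	D	0.5	0.150052325890944	0.300104651781887	0	0
SPK_074	D	0.5	0.216438064054153	0.432876128108306	0	0
SPK_075	D	0.5	0.312193998282681	0.624387996565363	0	1
SPK_076	D	0.5	0.450314010105639	0.900628020211279	0	1
SPK_077	D	0.5	0.649540698453174	1.29908139690635	1	1
SPK_078	D	0.5	0.936908711430192	1.87381742286038	1	2
SPK_079	D	0.5	1.35141329195258	2.70282658390516	1	3
SPK_080	D	0.5	1.94930185127454	3.89860370254907	2	4
SPK_081	D	0.5	2.81170662595175	5.62341325190349	3	6
SPK_082	D	0.5	4.05565415394844	8.11130830789687	4	8
SPK_083	D	0.5	5.84994553294533	11.6998910658907	6	12
SPK_084	D	0.5	8.43806237894074	16.8761247578815	8	17
SPK_085	D	0.5	12.1712067761846	24.3424135523692	12	24
SPK_086	D	0.5	17.5559586710757	35.1119173421513	18	35
SPK_087	D	0.5	25.3230177194585	50.6460354389171	25	51
SPK_088	D	0.5	36.5263577133223	73.0527154266446	37	73
SPK_089	D	0.5	52.6862486368036	105.372497273607	53	105
SPK_090	D	0.5	75.9955541476467	151.991108295293	76	152
SPK_091	D	0.5	109.617298624172	219.234597248345	110	219
SPK_092	D	0.5	158.113883008419	316.227766016838	158	316
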