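sample_id	habitat	array_id	spacer_count
MG00001	Engineered	A000001	1
MG00001	Engineered	A000002	2
MG00001	Engineered	A000003	1
MG00001	Engineered	A000004	1
MG00001	Engineered	A000005	1
MG00001	Engineered	A000006	1
MG00001	Engineered	A000007	1
MG00001	Engineered	A000008	2
MG00001	Engineered	A000009	1
MG00001	Engineered	A000010	1
MG00001	Engineered	A000011	1
MG00001	Engineered	A000012	1
MG00001	Engineered	A000013	1
MG00001	Engineered	A000014	1
MG00001	Engineered	A000015	1
MG00001	Engineered	A000016	1
MG00001	Engineered	A000017	1
MG00001	Engineered	A000018	1
MG00001	Engineered	A000019	1
MG00001	Engineered	A000020	1
MG00001	Engineered	A000021	1
MG00001	Engineered	A000022	1
MG00001	Engineered	A000023	1
MG00001	Engineered	A000024	1
MG00001	Engineered	A000025	3
MG00001	Engineered	A000026	1
MG00001	Engineered	A000027	1
MG00001	Engineered	A000028	1
MG00001	Engineered	A000029	1
MG00001	Engineered	A000030	1
MG00001	Engineered	A000031	1
MG00001	Engineered	A000032	1
MG00001	Engineered	A000033	1
MG00001	Engineered	A000034	1
MG00001	Engineered	A000035	1
MG00001	Engineered	A000036	2
MG00001	Engineered	A000037	1
MG00001	Engineered	A000038	1
MG00001	Engineered	A000039	1
MG00001	Engineered	A000040	1
MG00002	Host (human)	A000001	3
MG00002	Host (human)	A000002	1
MG00002	Host (human)	A000003	1
MG00002	Host (human)	A000004	1
MG00002	Host (human)	A000005	6
MG00002	Host (human)	A000006	1
MG00002	Host (human)	A000007	5
MG00002	Host (human)	A000008	2
MG00002	Host (human)	A000009	1
MG00002	Host (human)	A000010	1
MG00002	Host (human)	A000011	1
MG00002	Host (human)	A000012	1
MG00002	Host (human)	A000013	5
MG00002	Host (human)	A000014	1
MG00002	Host (human)	A000015	1
MG00002	Host (human)	A000016	3
MG00002	Host (human)	A000017	1
MG00002	Host (human)	A000018	1
MG00002	Host (human)	A000019	1
MG00002	Host (human)	A000020	1
MG00002	Host (human)	A000021	1
MG00002	Host (human)	A000022	1
MG00002	Host (human)	A000023	1
MG00002	Host (human)	A000024	1
MG00002	Host (human)	A000025	2
MG00002	Host (human)	A000026	1
MG00002	Host (human)	A000027	1
MG00002	Host (human)	A000028	2
MG00002	Host (human)	A000029	1
MG00002	Host (human)	A000030	1
MG00002	Host (human)	A000031	1
MG00002	Host (human)	A000032	1
MG00002	Host (human)	A000033	1
MG00002	Host (human)	A000034	3
MG00002	Host (human)	A000035	1
MG00002	Host (human)	A000036	4
MG00002	Host (human)	A000037	2
MG00002	Host (human)	A000038	5
MG00002	Host (human)	A000039	1
MG00002	Host (human)	A000040	7
MG00003	Marine	A000001	1
MG00003	Marine	A000002	3
MG00003	Marine	A000003	1
MG00003	Marine	A000004	1
MG00003	Marine	A000005	3
MG00003	Marine	A000006	1
MG00003	Marine	A000007	1
MG00003	Marine	A000008	1
MG00003	Marine	A000009	1
MG00003	Marine	A000010	1
MG00003	Marine	A000011	2
MG00003	Marine	A000012	1
MG00003	Marine	A000013	1
MG00003	Marine	A000014	1
MG00003	Marine	A000015	1
MG00003	Marine	A000016	2
MG00003	Marine	A000017	1
MG00003	Marine	A000018	1
MG00003	Marine	A000019	1
MG00003	Marine	A000020	1
MG00003	Marine	A000021	1
MG00003	Marine	A000022	1
MG00003	Marine	A000023	1
MG00003	Marine	A000024	1
MG00003	Marine	A000025	1
MG00003	Marine	A000026	2
MG00003	Marine	A000027	1
MG00003	Marine	A000028	1
MG00003	Marine	A000029	1
MG00003	Marine	A000030	1
MG00003	Marine	A000031	1
MG00003	Marine	A000032	1
MG00003	Marine	A000033	1
MG00003	Marine	A000034	2
MG00003	Marine	A000035	1
MG00003	Marine	A000036	1
MG00003	Marine	A000037	1
MG00003	Marine	A000038	2
MG00003	Marine	A000039	1
MG00003	Marine	A000040	1
MG00004	Terrestrial (soil)	A000001	1
MG00004	Terrestrial (soil)	A000002	1
MG00004	Terrestrial (soil)	A000003	1
MG00004	Terrestrial (soil)	A000004	1
MG00004	Terrestrial (soil)	A000005	1
MG00004	Terrestrial (soil)	A000006	1
MG00004	Terrestrial (soil)	A000007	1
MG00004	Terrestrial (soil)	A000008	1
MG00004	Terrestrial (soil)	A000009	2
MG00004	Terrestrial (soil)	A000010	1
MG00004	Terrestrial (soil)	A000011	1
MG00004	Terrestrial (soil)	A000012	1
MG00004	Terrestrial (soil)	A000013	1
MG00004	Terrestrial (soil)	A000014	1
MG00004	Terrestrial (soil)	A000015	1
MG00004	Terrestrial (soil)	A000016	1
MG00004	Terrestrial (soil)	A000017	1
MG00004	Terrestrial (soil)	A000018	1
MG00004	Terrestrial (soil)	A000019	3
MG00004	Terrestrial (soil)	A000020	1
MG00004	Terrestrial (soil)	A000021	1
MG00004	Terrestrial (soil)	A000022	1
MG00004	Terrestrial (soil)	A000023	1
MG00004	Terrestrial (soil)	A000024	1
MG00004	Terrestrial (soil)	A000025	1
MG00004	Terrestrial (soil)	A000026	1
MG00004	Terrestrial (soil)	A000027	8
MG00004	Terrestrial (soil)	A000028	1
MG00004	Terrestrial (soil)	A000029	1
MG00004	Terrestrial (soil)	A000030	1
MG00004	Terrestrial (soil)	A000031	1
MG00004	Terrestrial (soil)	A000032	1
MG00004	Terrestrial (soil)	A000033	2
MG00004	Terrestrial (soil)	A000034	1
MG00004	Terrestrial (soil)	A000035	1
MG00004	Terrestrial (soil)	A000036	1
MG00004	Terrestrial (soil)	A000037	3
MG00004	Terrestrial (soil)	A000038	1
MG00004	Terrestrial (soil)	A000039	1
MG00004	Terrestrial (soil)	A000040	1
MG00005	Host (human)	A000001	1
MG00005	Host (human)	A000002	1
MG00005	Host (human)	A000003	1
MG00005	Host (human)	A000004	1
MG00005	Host (human)	A000005	2
MG00005	Host (human)	A000006	1
MG00005	Host (human)	A000007	1
MG00005	Host (human)	A000008	2
MG00005	Host (human)	A000009	1
MG00005	Host (human)	A000010	1
MG00005	Host (human)	A000011	2
MG00005	Host (human)	A000012	4
MG00005	Host (human)	A000013	13
MG00005	Host (human)	A000014	1
MG00005	Host (human)	A000015	1
MG00005	Host (human)	A000016	1
MG00005	Host (human)	A000017	3
MG00005	Host (human)	A000018	1
MG00005	Host (human)	A000019	1
MG00005	Host (human)	A000020	1
MG00005	Host (human)	A000021	2
MG00005	Host (human)	A000022	1
MG00005	Host (human)	A000023	1
MG00005	Host (human)	A000024	1
MG00005	Host (human)	A000025	1
MG00005	Host (human)	A000026	1
MG00005	Host (human)	A000027	1
MG00005	Host (human)	A000028	3
MG00005	Host (human)	A000029	1
MG00005	Host (human)	A000030	1
MG00005	Host (human)	A000031	1
MG00005	Host (human)	A000032	1
MG00005	Host (human)	A000033	1
MG00005	Host (human)	A000034	1
MG00005	Host (human)	A000035	2
MG00005	Host (human)	A000036	1
MG00005	Host (human)	A000037	1
MG00005	Host (human)	A000038	5
MG00005	Host (human)	A000039	1
MG00005	Host (human)	A000040	1
MG00006	Marine	A000001	1
MG00006	Marine	A000002	6
MG00006	Marine	A000003	2
MG00006	Marine	A000004	1
MG00006	Marine	A000005	1
MG00006	Marine	A000006	1
MG00006	Marine	A000007	1
MG00006	Marine	A000008	1
MG00006	Marine	A000009	3
MG00006	Marine	A000010	1
MG00006	Marine	A000011	1
MG00006	Marine	A000012	1
MG00006	Marine	A000013	1
MG00006	Marine	A000014	1
MG00006	Marine	A000015	1
MG00006	Marine	A000016	1
MG00006	Marine	A000017	1
MG00006	Marine	A000018	1
MG00006	Marine	A000019	1
MG00006	Marine	A000020	2
MG00006	Marine	A000021	1
MG00006	Marine	A000022	1
MG00006	Marine	A000023	1
MG00006	Marine	A000024	1
MG00006	Marine	A000025	1
MG00006	Marine	A000026	1
MG00006	Marine	A000027	1
MG00006	Marine	A000028	1
MG00006	Marine	A000029	2
MG00006	Marine	A000030	1
MG00006	Marine	A000031	10
MG00006	Marine	A000032	1
MG00006	Marine	A000033	1
MG00006	Marine	A000034	3
MG00006	Marine	A000035	6
MG00006	Marine	A000036	1
MG00006	Marine	A000037	8
MG00006	Marine	A000038	2
MG00006	Marine	A000039	1
MG00006	Marine	A000040	1
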