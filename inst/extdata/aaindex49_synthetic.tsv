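property	A	C	D	E	F	G	H	I	K	L	M	N	P	Q	R	S	T	V	W	Y
KYTJ820101	0.7	0.7778	0.1111	0.1111	0.8111	0.4556	0.1444	1	0.0667	0.9222	0.7111	0.1111	0.3222	0.1111	0	0.4111	0.4222	0.9667	0.4	0.3556
HOPT810101	0.4531	0.375	1	1	0.1406	0.5312	0.4531	0.25	1	0.25	0.3281	0.5625	0.5312	0.5625	1	0.5781	0.4688	0.2969	0	0.1719
EISD840101	0.8072	0.7229	0.4177	0.4578	0.9518	0.7711	0.5462	1	0.2651	0.9197	0.8112	0.4498	0.6787	0.4297	0	0.6024	0.6345	0.9237	0.8554	0.7149
FAUJ830101	0.4049	0.7822	0.0736	0.1135	0.8589	0.3098	0.3497	0.862	0.0061	0.8313	0.6871	0.1258	0.5307	0.2423	0	0.2975	0.3896	0.684	1	0.6043
ZIMJ680101	0.2704	0.4821	0.2085	0.2117	0.8958	0.0326	0.3583	1	0.5212	0.8208	0.456	0.0293	0.8795	0	0.2704	0.0456	0.1759	0.5831	0.101	0.9674
PONP800101	0.3466	0.9672	0.0398	0.0913	0.6159	0.2834	0.4778	0.9297	0	0.7728	0.8267	0.0468	0.0913	0.1124	0.1616	0.1077	0.1991	1	0.5035	0.5831
JANJ780101	0.1406	0	0.5154	0.6023	0.1143	0.1029	0.4023	0.0834	1	0.1383	0.2057	0.5097	0.4114	0.608	0.9051	0.3029	0.3371	0.0937	0.2194	0.4537
MANP780101	0.4362	0.7778	0	0.214	0.6481	0.3251	0.2695	0.9918	0.1049	0.8333	0.7284	0.1173	0.107	0.1872	0.179	0.0782	0.1728	1	0.6337	0.5288
ARGP820101	0.2302	0.4038	0.1736	0.1774	0.7623	0.0264	0.2302	0.8377	0.434	0.5774	0.4453	0.0226	0.7358	0	0.2264	0.0189	0.0189	0.4981	1	0.7094
CIDH920105	0.3932	0.6475	0.0339	0	0.8441	0.1153	0.4746	1	0.2475	0.7729	0.7254	0.1254	0.3559	0.0136	0.2441	0.0576	0.1254	0.7695	0.9661	0.7627
GUYH850101	0.5509	0.1737	0.7196	0.732	0	0.6079	0.402	0.2457	0.8734	0.2333	0.1315	0.6452	0.7072	0.7618	1	0.6551	0.5434	0.2109	0.3995	0.4739
RADA880102	0.4804	0.3446	0.3446	0.1384	0.8903	0.3446	0.5927	0.8773	0.3655	0.8042	0.6893	0.342	0.3446	0.3264	0	0.3551	0.4151	0.6527	1	0.7702
BULH740101	0.8626	0.7672	0.8626	0.8244	0.0496	0.9389	0.8931	0.0763	0.8053	0	0.3779	0.9695	0.5649	1	0.8931	0.7901	0.7405	0.3435	0.1718	0.084
NOZY710101	0.1471	0	0	0	0.7353	0	0.1471	0.5294	0	0.5294	0.3824	0	0	0	0	0	0.1176	0.4412	1	0.6765
WOLS870101	0.5829	0.6577	1	0.9346	0	0.8353	0.8563	0.0561	0.9065	0.0853	0.2839	0.9509	0.4322	0.8294	0.9112	0.8037	0.6822	0.2605	0.0199	0.4124
GRAR740103	0.1677	0.3114	0.3054	0.479	0.7725	0	0.5569	0.6467	0.6946	0.6467	0.6108	0.3174	0.1766	0.491	0.7246	0.1737	0.3473	0.485	1	0.7964
BIGC670101	0.1645	0.3229	0.3239	0.4884	0.783	0	0.561	0.663	0.6942	0.663	0.6196	0.3976	0.3764	0.5388	0.7346	0.1877	0.3522	0.4924	1	0.8063
CHOC750101	0.1466	0.2996	0.3394	0.5181	0.8002	0	0.5894	0.5981	0.6127	0.5929	0.6098	0.4019	0.3674	0.5532	0.7921	0.191	0.3254	0.4398	1	0.8014
TSAJ990101	0.1568	0.238	0.3112	0.4613	0.7811	0	0.5763	0.6101	0.623	0.6107	0.6273	0.3604	0.3555	0.5111	0.778	0.187	0.3432	0.4576	1	0.8044
GOLD730102	0.1695	0.3138	0.3042	0.482	0.7725	0	0.5545	0.6497	0.6922	0.6497	0.612	0.3898	0.3725	0.5311	0.7257	0.1719	0.3485	0.4874	1	0.7964
KRIW790103	0.189	0.3065	0.2749	0.4261	0.7938	0	0.543	0.6426	0.6873	0.6426	0.6467	0.4034	0.288	0.5546	0.7216	0.2014	0.3526	0.4914	1	0.8062
DAWD720101	0.2857	0.3571	0.2857	0.6429	0.8571	0	0.7857	0.7143	0.9286	0.7143	0.7857	0.6429	0.7143	0.7857	1	0.3571	0.6429	0.6429	0.9286	0.9286
FASG760101	0.1085	0.3567	0.4493	0.5579	0.6977	0	0.62	0.4343	0.5506	0.4343	0.574	0.4417	0.3101	0.5503	0.7674	0.2324	0.341	0.3258	1	0.8216
MCMT640101	0.102	0.8411	0.2822	0.4058	0.6913	0	0.5128	0.4482	0.5006	0.4416	0.5088	0.3123	0.257	0.4129	0.6269	0.1493	0.2589	0.3273	1	0.7414
CHAM820101	0.1125	0.313	0.2567	0.3692	0.709	0	0.5623	0.4548	0.5355	0.4548	0.5403	0.3276	0.3203	0.4401	0.7115	0.1516	0.2641	0.3423	1	0.7286
GRAR740102	0.3951	0.0741	1	0.9136	0.037	0.5062	0.679	0.037	0.7901	0	0.0988	0.8272	0.3827	0.6914	0.6914	0.5309	0.4568	0.1235	0.0617	0.1605
ZIMJ680103	0	0.0285	0.9558	0.9596	0.0067	0	0.9923	0.0025	0.9519	0.0025	0.0275	0.065	0.0304	0.0679	1	0.0321	0.0319	0.0025	0.0404	0.031
RADA880108	0.4409	1	0.1496	0.1614	0.9646	0.3031	0.6575	0.9803	0	0.9409	0.9646	0.2756	0.4646	0.1772	0.1339	0.2677	0.3583	0.8937	0.811	0.5945
WOEC730101	0.2593	0.0741	1	0.9383	0.0123	0.3704	0.4321	0	0.642	0	0.0494	0.6296	0.2099	0.4568	0.5185	0.321	0.2099	0.0864	0.0494	0.0988
ZIMJ680104	0.4043	0.2854	0	0.0563	0.3392	0.4005	0.6033	0.4068	0.8723	0.4018	0.3717	0.3304	0.4418	0.3605	1	0.3642	0.3617	0.3992	0.3905	0.3617
FAUJ880111	0	0	0	0	0	0	1	0	1	0	0	0	0	0	1	0	0	0	0	0
FAUJ880112	0	0	1	1	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
KLEP840101	0.5	0.5	0	0	0.5	0.5	0.5	0.5	1	0.5	0.5	0.5	0.5	0.5	1	0.5	0.5	0.5	0.5	0.5
BHAR880101	0.249	0.2048	0.8675	0.8112	0.0763	1	0.1124	0.6707	0.6867	0.2811	0	0.6747	0.8594	0.7952	0.9398	0.8514	0.5984	0.3655	0.0402	0.502
VINM940101	0.404	0.0101	0.8283	0.9596	0.0556	0.6414	0.2323	0.1162	1	0.1566	0.2424	0.7273	0.7323	0.6717	0.5253	0.7172	0.4697	0.1364	0	0.1263
KARP850101	0.4754	0.1434	0.4426	0.6926	0.0205	0.8893	0.2336	0.3156	0.6885	0.1721	0.0902	0.7869	0.5328	0.9836	0.4631	1	0.6066	0.2336	0	0.1475
PONP800108	0.3926	1	0.0235	0.0738	0.5839	0.4295	0.3087	0.8826	0	0.8356	0.5067	0.0537	0.2584	0.1913	0.2752	0.2181	0.3121	0.9195	0.7047	0.6208
CHOP780201	0.9043	0.1383	0.4681	1	0.5957	0	0.4574	0.5426	0.6277	0.6809	0.9362	0.1064	0	0.5745	0.4362	0.2128	0.2766	0.5213	0.5426	0.1277
CHOP780202	0.3459	0.6165	0.1278	0	0.7594	0.2857	0.3759	0.9248	0.2782	0.6992	0.5113	0.391	0.1353	0.5489	0.4211	0.2857	0.6165	1	0.7519	0.8271
CHOP780203	0.2477	0.4495	0.9633	0.4404	0.1743	1	0.4404	0	0.6606	0.0275	0.1193	0.9083	1	0.4495	0.4954	0.8807	0.4679	0.1101	0.1193	0.6147
LEVM780101	0.8105	0.6211	0.5474	0.9684	0.5789	0.0421	0.7368	0.4737	0.7474	0.8211	1	0.4	0	0.7895	0.4632	0.3158	0.3158	0.4105	0.4947	0.2105
LEVM780102	0.3059	0.1176	0.0941	0.1294	0.8	0.3294	0.5176	0.9529	0.1529	0.4471	0.3882	0.1412	0	0.1882	0.4118	0.3647	0.6706	1	0.5882	0.7176
LEVM780103	0.24	0.2667	0.6667	0.3867	0.12	0.82	0.18	0.0667	0.3667	0.1133	0	0.58	1	0.38	0.3133	0.6067	0.42	0.04	0.2333	0.4267
GEIM800101	0.7253	0.1758	0.5165	0.9451	0.5495	0	0.7692	0.4615	0.7692	0.7473	1	0.1978	0	0.4835	0.4066	0.1648	0.1538	0.1978	0.6044	0.0879
ISOY800101	0.9078	0.4539	0.5319	0.9787	0.6879	0.1348	0.5532	0.5816	0.7163	0.7589	1	0.2482	0	0.7234	0.6525	0.2837	0.4326	0.4823	0.5674	0.3191
OOBM770101	0.2118	0	0.7821	0.7564	0.2587	0.2073	0.4236	0.1271	1	0.1044	0.1089	0.7186	0.5083	0.7776	0.8472	0.4266	0.4054	0.0817	0.2511	0.528
OOBM770102	0	0.0807	0.501	0.499	0.5569	0.0828	0.3913	0.4451	0.6832	0.1843	0.2091	0.4679	0.3478	0.5963	1	0.2215	0.3147	0.3106	0.7743	0.7743
YUTK870101	0.506	0.6548	0.506	0.5238	0.6667	0.4226	0.6012	1	0.4702	0.8929	0.7917	0.4881	0.4881	0.375	0	0.4405	0.5238	0.7143	0.5893	0.5238
YUTK870103	0.971	0.9758	0.9323	0.9753	0.9291	0.9796	0.993	1	0.9646	0.9989	0.9726	0.9382	0.9753	0.9629	0	0.9436	0.942	0.9828	0.9232	0.9662
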