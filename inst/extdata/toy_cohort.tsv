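subject	group	mean_thickness	r01	r02	r03	r04	r05	r06	r07	r08
HC_01	HC	2.5459096	2.5098181	2.6735352	2.6167174	2.6096028	2.5938171	2.5655776	2.4271749	2.3710339
HC_02	HC	2.5691904	2.6441525	2.6200847	2.5551364	2.6823035	2.7507559	2.7597403	2.255836	2.2855139
HC_03	HC	2.4809368	2.5954234	2.5808269	2.4616402	2.1830249	2.4603144	2.4403143	2.5213717	2.6045789
HC_04	HC	2.4392735	2.2999122	2.4659844	2.5148998	2.5069413	2.2766017	2.3880559	2.4240587	2.6377341
HC_05	HC	2.3494982	2.3729836	2.4545183	2.386485	2.4719559	2.0484072	2.2395186	2.4619513	2.360166
HC_06	HC	2.5693556	2.422088	2.3523677	2.7040362	2.6163084	2.6923362	2.6486283	2.4630552	2.6560246
HC_07	HC	2.3621223	2.3172527	2.2398399	2.3961239	2.313866	2.3276312	2.4865834	2.3805209	2.4351605
HC_08	HC	2.4889991	2.4202815	2.3584637	2.2664407	2.155935	2.7540092	2.5584044	2.6252104	2.7732476
HC_09	HC	2.4382145	2.1959722	2.1811734	2.1361871	2.5952907	2.4862808	2.3776384	2.6964334	2.8367398
HC_10	HC	2.586997	2.5018841	2.6719264	2.6649504	2.6395344	2.7162452	2.6167242	2.3900583	2.4946532
SZND_01	SZND	2.3700351	2.2032427	2.2241856	2.5253914	2.514751	2.4746657	2.3879943	2.3195773	2.3104727
SZND_02	SZND	2.6202569	2.4117467	2.5225843	2.667607	2.8620717	2.658302	2.6729241	2.6983989	2.4684203
SZND_03	SZND	2.2755137	2.3077099	2.2635259	2.1389817	2.1888938	2.3203146	2.2949496	2.2573841	2.4323502
SZND_04	SZND	2.5620361	2.4296457	2.4799191	2.7355611	2.6967714	2.7466588	2.5829605	2.4358677	2.3889044
SZND_05	SZND	2.6718443	2.7133713	2.6098542	2.5465221	2.5006296	2.9345641	2.7238732	2.7118461	2.6340936
SZND_06	SZND	2.5510761	2.5797724	2.4282026	2.6293741	2.4779618	2.4832673	2.7228621	2.6334927	2.4536761
SZND_07	SZND	2.4420758	2.3154506	2.4341758	2.3457724	2.4598555	2.5178324	2.4937919	2.4851354	2.4845927
SZND_08	SZND	2.6764446	2.5236562	2.4385082	2.9126433	2.8884792	2.553823	2.375017	2.9228776	2.796552
SZND_09	SZND	2.5421726	2.3955201	2.4162452	2.5605815	2.4897016	2.66379	2.768666	2.5601821	2.4826938
SZND_10	SZND	2.4491643	2.5574081	2.3801193	2.4087124	2.510433	2.4502841	2.413181	2.3399338	2.5332425
SZD_01	SZD	2.5763506	2.6281861	2.5415972	2.3587931	2.5717448	2.4958493	2.4522593	2.834258	2.7281171
SZD_02	SZD	2.6390879	2.5882771	2.6293201	2.6109632	2.5745413	2.8116615	2.8455814	2.3996508	2.6527075
SZD_03	SZD	2.5117816	2.5075118	2.5758539	2.4970659	2.6792459	2.3326079	2.6818751	2.4097725	2.4103203
SZD_04	SZD	2.2935902	2.0866062	2.2789203	2.5277223	2.4744782	2.2018641	2.4297092	2.130095	2.2193266
SZD_05	SZD	2.5147441	2.43066	2.4043009	2.5192149	2.3264333	2.6971777	2.4947349	2.735596	2.5098347
SZD_06	SZD	2.7028637	2.8039635	2.7937895	2.5162806	2.6324929	2.4961227	2.8603875	2.6627414	2.8571312
SZD_07	SZD	2.5307726	2.6360641	2.4939218	2.4260725	2.5093759	2.5049226	2.5153783	2.4249688	2.7354768
SZD_08	SZD	2.4409427	2.4687041	2.5129313	2.2791116	2.2772043	2.5599131	2.5580761	2.4369724	2.4346284
SZD_09	SZD	2.2903321	2.4162712	2.4987219	2.0990681	2.2711946	2.1666159	2.2687303	2.2277954	2.3742589
SZD_10	SZD	2.6211186	2.7383467	2.5256661	2.6182449	2.6925303	2.5163683	2.4922862	2.8233283	2.562178
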