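subject_id	age	age_c	mfq_fof	y1	y2	y3
S001	61.355567	-8.644433	2.176221	0.418393	0.153986	-0.076505
S002	69.681852	-0.318148	2.152803	0.176725	0.223181	-0.17207
S003	79.913077	9.913077	3.29045	0.672472	NA	NA
S004	59.598414	-10.401586	2.86126	0.005108	-0.120138	-0.437484
S005	67.635894	-2.364106	3.385347	0.154984	-0.08909	NA
S006	69.277811	-0.722189	2.941204	0.296298	NA	NA
S007	73.675988	3.675988	2.165666	0.27401	NA	NA
S008	66.403613000000007	-3.596387	4.174192	0.306703	NA	0.15883
S009	82.162914	12.162914	3.691546	0.368271	0.026502	-0.087975
S010	67.183519	-2.816481	3.946501	0.123984	-0.403898	NA
S011	71.46973	1.46973	1.709517	0.18452	NA	NA
S012	75.715252	5.7152520000000004	3.89517	0.492026	0.293488	-0.221334
S013	65.221928	-4.778072	1.451299	0.389445	NA	0.662745
S014	60.277246	-9.722754	2.505204	0.74957	0.710956	NA
S015	81.086496	11.086496	1.743718	0.246015	0.406352	NA
S016	52.11306	-17.88694	0.993524	0.613065	0.179177	0.273074
S017	74.953302	4.953302	4.642918	0.865282	0.440302	0.362562
S018	68.532379	-1.467621	2.396138	0.161432	NA	NA
S019	75.942996	5.942996	2.731246	0.896707	NA	NA
S020	71.581528	1.581528	2.638285	0.261428	0.180661	0.060926
S021	82.657858	12.657858	3.341577	0.185759	NA	-0.160432
S022	59.08205	-10.91795	4.442945	0.695595	NA	NA
S023	79.924418	9.924418	4.515883	0.468903	0.541049	0.437257
S024	82.014863	12.014863	1.914721	0.518038	NA	NA
S025	68.294019	-1.705981	1.756229	0.500471	NA	NA
S026	51.563166	-18.436834	1.616647	0.499479	0.094044	NA
S027	71.925149	1.925149	1.851701	0.262668	0.303274	0.109528
S028	63.651425	-6.348575	4.766133	0.518876	0.217686	NA
S029	74.308883	4.308883	2.996995	0.00941	NA	NA
S030	70.488044	0.488044	2.224238	-0.06619	-0.347256	NA
S031	73.90922	3.90922	2.443601	0.17705	-0.26334	-0.335975
S032	70.713262	0.713262	3.96641	0.393671	0.141527	-0.228315
S033	76.404216	6.404216	3.226952	0.549543	NA	NA
S034	66.060078	-3.939922	2.704348	0.643077	0.46364	0.857376
S035	62.271111	-7.728889	2.308702	0.098958	-0.12801	NA
S036	63.658324	-6.341676	2.206452	-0.10677	-0.273081	NA
S037	55.37035	-14.62965	4.845426	0.350967	-0.247073	-0.61943
S038	61.312542	-8.687458	3.844262	0.639729	NA	NA
S039	63.939768	-6.060232	4.810277	0.565135	NA	NA
S040	66.350953	-3.649047	2.606996	-0.25389	-0.670707	-0.941067
S041	65.292233	-4.707767	2.671113	0.192558	NA	NA
S042	53.91496	-16.08504	2.056473	0.647914	NA	NA
S043	61.775243	-8.224757	2.762301	0.771337	NA	NA
S044	81.752218	11.752218	3.418988	0.482771	NA	NA
S045	73.030126	3.030126	4.224427	0.430446	NA	NA
S046	82.194398	12.194398	3.502885	0.762617	NA	NA
S047	65.895328	-4.104672	3.404555	-0.049106	NA	NA
S048	67.554039	-2.445961	4.108401	0.734246	NA	NA
S049	66.832823	-3.167177	4.032366	0.208413	0.173146	NA
S050	59.090615	-10.909385	3.086953	0.454078	0.282935	NA
S051	61.801266	-8.198734	2.278101	0.205751	NA	NA
S052	82.548447	12.548447	4.117694	0.114675	NA	NA
S053	63.915264	-6.084736	3.116281	0.541768	0.446165	0.277322
S054	77.826118	7.826118	4.542477	0.439596	NA	NA
S055	60.217879	-9.782121	2.598573	0.578337	NA	NA
S056	53.875308	-16.124692	2.04118	0.370858	0.103257	NA
S057	65.760253	-4.239747	3.47872	0.633024	0.607489	0.07582
S058	75.377348	5.377348	2.381425	-0.170823	NA	-0.529102
S059	76.859128	6.859128	3.570714	0.642592	0.236485	0.032735
S060	80.433255	10.433255	1.425858	0.269428	0.247254	NA
S061	54.965932	-15.034068	1.409245	0.562568	0.828891	0.788936
S062	82.387054	12.387054	3.617055	0.356349	NA	NA
S063	62.833527	-7.166473	3.290917	0.416021	NA	0.145915
S064	69.476259	-0.523741	3.78173	-0.16493	NA	NA
S065	72.146364	2.146364	1.163622	0.092477	-0.390629	-0.820047
S066	61.940612	-8.059388	4.091736	0.312273	NA	NA
S067	53.684794	-16.315206	4.080774	0.583899	0.241252	NA
S068	64.554038	-5.445962	3.92793	0.618025	NA	NA
S069	68.905733	-1.094267	3.704829	0.401327	NA	NA
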