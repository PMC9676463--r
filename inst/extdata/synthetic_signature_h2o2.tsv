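gene_id	log2fc
AT5G67570	-0.729
AT4G71135	0.416
AT4G70746	0.126
AT3G55860	0.823
AT5G05152	-0.302
AT2G18684	0.016
AT1G79761	0.809
AT4G22961	-0.446
AT1G47554	0.853
AT1G13651	0.381
AT2G13227	-0.373
AT1G31859	0.909
AT5G78031	-0.705
AT3G26102	0.815
AT5G74934	-1.532
AT3G17065	0.693
AT1G45077	0.141
AT1G52243	0.897
AT1G77258	2.01
AT2G57249	-1.133
AT1G74706	-0.57
AT3G24817	1.213
AT1G77694	-0.031
AT1G72786	0.155
AT4G14682	0.736
AT5G66261	-0.733
AT2G36124	-1.314
AT4G32525	-0.407
AT5G71463	0.584
AT1G31965	0.259
AT2G03626	-1.237
AT3G35931	0.7
AT4G06112	1.053
AT5G48756	0.803
AT3G33146	0.425
AT4G34491	0.093
AT5G18945	-1.311
AT2G20644	-1.425
AT5G06042	-1.036
AT4G13218	1.336
AT3G33151	0.29
AT3G02556	0.419
AT5G59896	-0.849
AT1G09225	-1.056
AT3G04645	-1.233
AT5G09251	-0.088
AT1G47342	0.88
AT5G48806	0.323
AT1G53789	0.084
AT5G55718	-0.178
AT2G43742	-0.044
AT3G45198	1.161
AT5G41428	1.986
AT5G44336	-0.002
AT3G59059	1.202
AT4G48449	-1.28
AT3G55862	-0.817
AT4G37202	0.34
AT3G69321	-0.452
AT3G69801	0.195
AT4G37375	1.087
AT1G68112	-1.042
AT5G46465	0.647
AT1G25458	-1.832
AT5G35247	0.431
AT1G35631	0.88
AT4G10072	-1.039
AT5G27204	1.102
AT5G54378	0.078
AT2G05732	-1.008
AT3G78075	0.139
AT1G64258	0.462
AT3G41986	0.068
AT1G68573	0.148
AT5G50295	0.635
AT5G45464	-0.181
AT1G25243	-2.077
AT2G70571	-1.438
AT3G25557	0.374
AT1G78174	-0.482
AT3G25894	-0.058
AT3G33441	-0.047
AT5G35809	0.212
AT4G19012	-0.119
AT2G50807	0.506
AT2G43025	0.747
AT3G07347	0.975
AT1G30937	0.119
AT1G08347	-0.477
AT1G33126	0.455
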