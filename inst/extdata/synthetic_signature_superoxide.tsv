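gene_id	log2fc
AT5G67570	0.668
AT4G71135	0.095
AT4G70746	0.625
AT3G55860	0.698
AT5G05152	-0.79
AT2G18684	0.066
AT1G79761	0.635
AT4G22961	-0.406
AT1G47554	1.512
AT1G13651	0.115
AT2G13227	0.86
AT1G31859	-0.973
AT5G78031	0.382
AT3G26102	-0.489
AT5G74934	0.211
AT3G17065	-1.275
AT1G45077	0.642
AT1G52243	0.941
AT1G77258	-1.765
AT2G57249	-0.065
AT1G74706	-0.308
AT3G24817	-0.862
AT1G77694	0.231
AT1G72786	-0.838
AT4G14682	-2.626
AT5G66261	0.614
AT2G36124	1.812
AT4G32525	1.227
AT5G71463	1.878
AT1G31965	0.637
AT2G03626	-0.575
AT3G35931	-1.282
AT4G06112	0.607
AT5G48756	0.024
AT3G33146	1.452
AT4G34491	-0.771
AT5G18945	-0.661
AT2G20644	0.333
AT5G06042	-0.646
AT4G13218	-1.383
AT3G33151	-0.29
AT3G02556	-0.17
AT5G59896	0.272
AT1G09225	-0.205
AT3G04645	-0.463
AT5G09251	1.228
AT1G47342	-1.123
AT5G48806	0.557
AT1G53789	-0.782
AT5G55718	0.099
AT2G43742	0.482
AT3G45198	-0.92
AT5G41428	-1.229
AT5G44336	0.461
AT3G59059	0.245
AT4G48449	1.199
AT3G55862	0.25
AT4G37202	0.299
AT3G69321	-1.34
AT3G69801	0.045
AT4G37375	0.809
AT1G68112	-0.866
AT5G46465	0.027
AT1G25458	0.331
AT5G35247	0.892
AT1G35631	-1.433
AT4G10072	-0.448
AT5G27204	-1.662
AT5G54378	-0.431
AT2G05732	0.359
AT3G78075	-0.311
AT1G64258	0.744
AT3G41986	2.242
AT1G68573	-1.048
AT5G50295	-0.699
AT5G45464	-0.798
AT1G25243	1.486
AT2G70571	-0.196
AT3G25557	-0.094
AT1G78174	0.107
AT3G25894	1.338
AT3G33441	0.827
AT5G35809	0.344
AT4G19012	0.223
AT2G50807	0.535
AT2G43025	0.215
AT3G07347	0.913
AT1G30937	0.209
AT1G08347	-0.636
AT1G33126	-1.645
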