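gene_id	log2fc
AT5G67570	1.241
AT4G71135	-1.891
AT4G70746	1.287
AT3G55860	-1.39
AT5G05152	0.22
AT2G18684	-0.283
AT1G79761	2.406
AT4G22961	-0.855
AT1G47554	-0.425
AT1G13651	2.374
AT2G13227	-0.333
AT1G31859	-1.963
AT5G78031	-0.3
AT3G26102	-0.847
AT5G74934	0.584
AT3G17065	-0.949
AT1G45077	0.065
AT1G52243	0.85
AT1G77258	-1.162
AT2G57249	0.293
AT1G74706	0.406
AT3G24817	-1.376
AT1G77694	-0.119
AT1G72786	0.524
AT4G14682	-2.633
AT5G66261	4.619
AT2G36124	0.032
AT4G32525	-0.089
AT5G71463	1.833
AT1G31965	0.206
AT2G03626	-0.142
AT3G35931	-0.359
AT4G06112	-0.18
AT5G48756	-0.927
AT3G33146	2.22
AT4G34491	0.673
AT5G18945	-0.59
AT2G20644	1.848
AT5G06042	0.212
AT4G13218	-0.959
AT3G33151	-0.14
AT3G02556	-0.481
AT5G59896	-1.2
AT1G09225	0.321
AT3G04645	-0.804
AT5G09251	1.509
AT1G47342	0.353
AT5G48806	-0.841
AT1G53789	0.184
AT5G55718	0.325
AT2G43742	0.237
AT3G45198	-1.393
AT5G41428	0.841
AT5G44336	1.901
AT3G59059	-0.611
AT4G48449	1.107
AT3G55862	-1.195
AT4G37202	-0.506
AT3G69321	-0.606
AT3G69801	1.135
AT4G37375	-0.441
AT1G68112	0.284
AT5G46465	0.468
AT1G25458	0.936
AT5G35247	0.434
AT1G35631	-0.688
AT4G10072	1.023
AT5G27204	-2.66
AT5G54378	-0.238
AT2G05732	0.739
AT3G78075	-1.095
AT1G64258	0.497
AT3G41986	1.88
AT1G68573	-1.595
AT5G50295	-1.512
AT5G45464	0.535
AT1G25243	2.763
AT2G70571	1.123
AT3G25557	0.345
AT1G78174	-1.02
AT3G25894	0.423
AT3G33441	0.001
AT5G35809	-0.171
AT4G19012	0.392
AT2G50807	0.846
AT2G43025	-1.384
AT3G07347	-1.469
AT1G30937	-0.311
AT1G08347	0.458
AT1G33126	-1.987
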