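channel	state	cn_min	cn_max	len_min	len_max
0:homdel:0-100kb	homdel	0	0	0	1e+05
0:homdel:100kb-1Mb	homdel	0	0	1e+05	1e+06
0:homdel:>1Mb	homdel	0	0	1e+06	Inf
1:LOH:0-100kb	LOH	1	1	0	1e+05
1:LOH:100kb-1Mb	LOH	1	1	1e+05	1e+06
1:LOH:1Mb-10Mb	LOH	1	1	1e+06	1e+07
1:LOH:10Mb-40Mb	LOH	1	1	1e+07	4e+07
1:LOH:>40Mb	LOH	1	1	4e+07	Inf
2:LOH:0-100kb	LOH	2	2	0	1e+05
2:LOH:100kb-1Mb	LOH	2	2	1e+05	1e+06
2:LOH:1Mb-10Mb	LOH	2	2	1e+06	1e+07
2:LOH:10Mb-40Mb	LOH	2	2	1e+07	4e+07
2:LOH:>40Mb	LOH	2	2	4e+07	Inf
3-4:LOH:0-100kb	LOH	3	4	0	1e+05
3-4:LOH:100kb-1Mb	LOH	3	4	1e+05	1e+06
3-4:LOH:1Mb-10Mb	LOH	3	4	1e+06	1e+07
3-4:LOH:10Mb-40Mb	LOH	3	4	1e+07	4e+07
3-4:LOH:>40Mb	LOH	3	4	4e+07	Inf
5-8:LOH:0-100kb	LOH	5	8	0	1e+05
5-8:LOH:100kb-1Mb	LOH	5	8	1e+05	1e+06
5-8:LOH:1Mb-10Mb	LOH	5	8	1e+06	1e+07
5-8:LOH:10Mb-40Mb	LOH	5	8	1e+07	4e+07
5-8:LOH:>40Mb	LOH	5	8	4e+07	Inf
9+:LOH:0-100kb	LOH	9	Inf	0	1e+05
9+:LOH:100kb-1Mb	LOH	9	Inf	1e+05	1e+06
9+:LOH:1Mb-10Mb	LOH	9	Inf	1e+06	1e+07
9+:LOH:10Mb-40Mb	LOH	9	Inf	1e+07	4e+07
9+:LOH:>40Mb	LOH	9	Inf	4e+07	Inf
2:het:0-100kb	het	2	2	0	1e+05
2:het:100kb-1Mb	het	2	2	1e+05	1e+06
2:het:1Mb-10Mb	het	2	2	1e+06	1e+07
2:het:10Mb-40Mb	het	2	2	1e+07	4e+07
2:het:>40Mb	het	2	2	4e+07	Inf
3-4:het:0-100kb	het	3	4	0	1e+05
3-4:het:100kb-1Mb	het	3	4	1e+05	1e+06
3-4:het:1Mb-10Mb	het	3	4	1e+06	1e+07
3-4:het:10Mb-40Mb	het	3	4	1e+07	4e+07
3-4:het:>40Mb	het	3	4	4e+07	Inf
5-8:het:0-100kb	het	5	8	0	1e+05
5-8:het:100kb-1Mb	het	5	8	1e+05	1e+06
5-8:het:1Mb-10Mb	het	5	8	1e+06	1e+07
5-8:het:10Mb-40Mb	het	5	8	1e+07	4e+07
5-8:het:>40Mb	het	5	8	4e+07	Inf
9+:het:0-100kb	het	9	Inf	0	1e+05
9+:het:100kb-1Mb	het	9	Inf	1e+05	1e+06
9+:het:1Mb-10Mb	het	9	Inf	1e+06	1e+07
9+:het:10Mb-40Mb	het	9	Inf	1e+07	4e+07
9+:het:>40Mb	het	9	Inf	4e+07	Inf
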