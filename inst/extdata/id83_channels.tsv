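channel	indel_type	length_bin	motif	unit_min	unit_max
1:Del:C:0	Del	1	C	1	1
1:Del:C:1	Del	1	C	2	2
1:Del:C:2	Del	1	C	3	3
1:Del:C:3	Del	1	C	4	4
1:Del:C:4	Del	1	C	5	5
1:Del:C:5	Del	1	C	6	Inf
1:Del:T:0	Del	1	T	1	1
1:Del:T:1	Del	1	T	2	2
1:Del:T:2	Del	1	T	3	3
1:Del:T:3	Del	1	T	4	4
1:Del:T:4	Del	1	T	5	5
1:Del:T:5	Del	1	T	6	Inf
1:Ins:C:0	Ins	1	C	0	0
1:Ins:C:1	Ins	1	C	1	1
1:Ins:C:2	Ins	1	C	2	2
1:Ins:C:3	Ins	1	C	3	3
1:Ins:C:4	Ins	1	C	4	4
1:Ins:C:5	Ins	1	C	5	Inf
1:Ins:T:0	Ins	1	T	0	0
1:Ins:T:1	Ins	1	T	1	1
1:Ins:T:2	Ins	1	T	2	2
1:Ins:T:3	Ins	1	T	3	3
1:Ins:T:4	Ins	1	T	4	4
1:Ins:T:5	Ins	1	T	5	Inf
2:Del:R:0	Del	2	R	1	1
2:Del:R:1	Del	2	R	2	2
2:Del:R:2	Del	2	R	3	3
2:Del:R:3	Del	2	R	4	4
2:Del:R:4	Del	2	R	5	5
2:Del:R:5	Del	2	R	6	Inf
3:Del:R:0	Del	3	R	1	1
3:Del:R:1	Del	3	R	2	2
3:Del:R:2	Del	3	R	3	3
3:Del:R:3	Del	3	R	4	4
3:Del:R:4	Del	3	R	5	5
3:Del:R:5	Del	3	R	6	Inf
4:Del:R:0	Del	4	R	1	1
4:Del:R:1	Del	4	R	2	2
4:Del:R:2	Del	4	R	3	3
4:Del:R:3	Del	4	R	4	4
4:Del:R:4	Del	4	R	5	5
4:Del:R:5	Del	4	R	6	Inf
5:Del:R:0	Del	5	R	1	1
5:Del:R:1	Del	5	R	2	2
5:Del:R:2	Del	5	R	3	3
5:Del:R:3	Del	5	R	4	4
5:Del:R:4	Del	5	R	5	5
5:Del:R:5	Del	5	R	6	Inf
2:Ins:R:0	Ins	2	R	0	0
2:Ins:R:1	Ins	2	R	1	1
2:Ins:R:2	Ins	2	R	2	2
2:Ins:R:3	Ins	2	R	3	3
2:Ins:R:4	Ins	2	R	4	4
2:Ins:R:5	Ins	2	R	5	Inf
3:Ins:R:0	Ins	3	R	0	0
3:Ins:R:1	Ins	3	R	1	1
3:Ins:R:2	Ins	3	R	2	2
3:Ins:R:3	Ins	3	R	3	3
3:Ins:R:4	Ins	3	R	4	4
3:Ins:R:5	Ins	3	R	5	Inf
4:Ins:R:0	Ins	4	R	0	0
4:Ins:R:1	Ins	4	R	1	1
4:Ins:R:2	Ins	4	R	2	2
4:Ins:R:3	Ins	4	R	3	3
4:Ins:R:4	Ins	4	R	4	4
4:Ins:R:5	Ins	4	R	5	Inf
5:Ins:R:0	Ins	5	R	0	0
5:Ins:R:1	Ins	5	R	1	1
5:Ins:R:2	Ins	5	R	2	2
5:Ins:R:3	Ins	5	R	3	3
5:Ins:R:4	Ins	5	R	4	4
5:Ins:R:5	Ins	5	R	5	Inf
2:Del:M:1	Del	2	M	1	1
3:Del:M:1	Del	3	M	1	1
3:Del:M:2	Del	3	M	2	2
4:Del:M:1	Del	4	M	1	1
4:Del:M:2	Del	4	M	2	2
4:Del:M:3	Del	4	M	3	3
5:Del:M:1	Del	5	M	1	1
5:Del:M:2	Del	5	M	2	2
5:Del:M:3	Del	5	M	3	3
5:Del:M:4	Del	5	M	4	4
5:Del:M:5	Del	5	M	5	Inf
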