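position	rate_cM_Mb	map_cM
0	0.8	0.00
500000	1.6	0.40
1000000	0.4	1.20
1500000	2.8	1.40
2000000	1.0	2.80
2500000	0.6	3.30
3000000	2.2	3.60
3500000	1.2	4.70
4000000	0.5	5.30
4500000	1.3	5.55
5000000	0.8	6.20
5500000	1.6	6.60
6000000	0.4	7.40
6500000	2.8	7.60
7000000	1.0	9.00
7500000	0.6	9.50
8000000	2.2	9.80
8500000	1.2	10.90
9000000	0.5	11.50
9500000	1.3	11.75
10000000	1.3	12.40
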