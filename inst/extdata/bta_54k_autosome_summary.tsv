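chrom	length_mb	n_snp
1	160.89	2729
2	138.92	2221
3	125.41	2067
4	120.39	2031
5	124.59	1740
6	119.01	2099
7	112.37	1809
8	115.59	1940
9	104.64	1639
10	103.09	1752
11	106.97	1858
12	89.17	1338
13	83.84	1434
14	83.15	1409
15	83.81	1371
16	80.09	1283
17	74.89	1324
18	65.16	1101
19	62.83	1131
20	72.00	1314
21	68.46	1110
22	60.14	1047
23	51.73	895
24	62.77	1053
25	43.23	825
26	50.95	871
27	45.33	801
28	46.06	783
29	50.53	863
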