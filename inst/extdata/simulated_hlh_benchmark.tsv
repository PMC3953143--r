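no	id	aa	expected	measured	diff	rel_err	dp_eps
1	1ARO	1	7.6	7.4396	0.1604	2.1	1.00
2	1B0B	1	7.6	7.7384	0.1384	1.8	1.25
3	1BGP	1	7.6	7.6755	0.0755	1.0	1.30
4	1BQB	1	7.6	8.0995	0.4995	6.6	2.30
5	1GUX	1	7.6	7.8102	0.2102	2.8	6.00
6	1B43	2	11.4	11.4264	0.0264	0.2	0.45
7	1B89	2	11.4	11.8811	0.4811	4.2	2.55
8	1BD8	2	11.4	11.3578	0.0422	0.4	0.00
9	1BPY	2	11.4	11.4800	0.0800	0.7	2.25
10	1BR1	2	11.4	11.1461	0.2539	2.2	0.00
11	1FJL	3	15.2	15.4724	0.2724	1.8	1.35
12	1FK5	3	15.2	14.9523	0.2477	1.6	0.00
13	1FUR	3	15.2	15.2643	0.0643	0.4	6.00
14	1H0M	3	15.2	15.3601	0.1601	1.1	2.70
15	1DU0	3	15.2	14.9900	0.2100	1.4	0.60
16	1A87	4	19.0	18.8901	0.1099	0.6	0.95
17	1AIH	4	19.0	19.2057	0.2057	1.1	6.00
18	1AJ8	4	19.0	4.1231	14.8769	78.3	0.00
19	1BMT	4	19.0	19.2313	0.2313	1.2	5.55
20	1BOU	4	19.0	18.9609	0.0391	0.2	0.70
21	1D8L	5	22.8	23.1403	0.3403	1.5	0.60
22	1DI1	5	22.8	22.9243	0.1243	0.5	4.25
23	1DLC	5	22.8	22.5618	0.2382	1.0	0.00
24	1DNP	5	22.8	23.1044	0.3044	1.3	1.70
25	1DP7	5	22.8	22.7786	0.0214	0.1	2.10
26	1CQX	6	26.6	26.2583	0.3417	1.3	0.00
27	1CSH	6	26.6	26.9157	0.3157	1.2	1.85
28	1HM6	6	26.6	7.1461	18.8539	26.3	0.00
29	1MW8	6	26.6	26.2419	0.3581	1.3	0.00
30	1O6L	6	26.6	26.6271	0.0271	0.1	6.00
31	1DJX	7	30.4	30.7842	0.3842	1.3	3.85
32	1E5Q	7	30.4	30.5342	0.1342	0.4	4.65
33	1FFV	7	30.4	30.0703	0.3297	1.1	2.50
34	1H99	7	30.4	30.1897	0.2103	0.7	0.00
35	1IRX	7	30.4	30.7213	0.3213	1.1	6.00
36	1O6L	8	34.2	34.6762	0.4762	1.4	6.00
37	1QVR	8	34.2	34.2838	0.0838	0.2	0.60
38	1S0V	8	34.2	34.2505	0.0505	0.1	0.95
39	1TAU	8	34.2	34.3267	0.1267	0.4	0.70
40	1U09	8	34.2	34.1468	0.0532	0.2	2.05
41	1D6M	9	38.0	38.1574	0.1574	0.4	1.00
42	1FUR	9	38.0	38.3249	0.3249	0.9	2.85
43	1H32	9	38.0	38.1491	0.1491	0.4	0.70
44	1QPC	9	38.0	37.9111	0.0889	0.2	0.00
45	1SU8	9	38.0	37.9337	0.0663	0.2	0.65
46	1QRT	10	41.8	41.7369	0.0631	0.2	0.75
47	1R1H	10	41.8	41.3131	0.4869	1.2	0.00
48	1RJB	10	41.8	41.8528	0.0528	0.1	1.00
49	1XO0	10	41.8	41.8814	0.0814	0.2	1.05
50	2B63	10	41.8	41.4589	0.3411	0.8	4.60
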