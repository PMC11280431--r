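mirna_id	log2fc	logcpm	lr	p_value	fdr	fc	direction
miR-27a-5p	4.237	8.517	60.574	7.09e-15	9.56e-12	18.857	up
miR-200b-5p	2.840	8.773	43.317	4.65e-11	3.14e-8	7.161	up
miR-375-3p	2.438	11.469	41.710	1.06e-10	3.57e-8	5.420	up
miR-200c-3p	1.823	12.823	39.722	2.93e-10	6.59e-8	3.538	up
miR-193a-5p	2.718	7.332	37.110	1.12e-9	1.88e-7	6.579	up
miR-205-5p	3.358	10.035	35.724	2.27e-9	3.41e-7	10.257	up
miR-92a-1-5p	3.339	3.944	28.781	8.10e-8	6.43e-6	10.119	up
miR-2110	2.480	4.822	28.131	1.13e-7	8.50e-6	5.577	up
miR-5100	5.146	5.276	27.980	1.23e-7	8.71e-6	35.400	up
miR-625-3p	1.567	6.313	26.049	3.33e-7	1.95e-5	2.962	up
miR-125a-5p	1.830	13.350	23.467	1.27e-6	6.13e-5	3.556	up
miR-671-3p	1.764	5.307	23.134	1.51e-6	7.04e-5	3.396	up
miR-29b-1-5p	2.515	3.417	22.098	2.59e-6	1.03e-4	5.718	up
miR-23a-5p	3.774	3.797	21.943	2.81e-6	1.04e-4	13.682	up
miR-484	1.278	9.722	16.749	4.27e-5	8.73e-4	2.425	up
miR-495-3p	-1.904	7.556	40.765	1.72e-10	4.64e-8	0.267	down
miR-381-3p	-1.824	6.177	37.324	1.00e-9	1.88e-7	0.282	down
miR-369-3p	-2.102	6.561	31.711	1.79e-8	2.20e-6	0.233	down
miR-451a	-2.672	12.793	30.373	3.57e-8	3.33e-6	0.157	down
miR-337-3p	-1.643	6.122	29.255	6.34e-8	5.35e-6	0.320	down
miR-376c-3p	-1.944	3.657	27.124	1.91e-7	1.29e-5	0.260	down
miR-127-5p	-1.676	7.121	26.997	2.04e-7	1.31e-5	0.313	down
miR-4521	-1.672	4.424	22.549	2.05e-6	8.92e-5	0.314	down
miR-98-3p	-1.555	5.206	22.025	2.69e-6	1.04e-4	0.340	down
miR-539-3p	-2.135	5.598	20.607	5.64e-6	1.77e-4	0.228	down
miR-136-3p	-1.753	7.573	20.357	6.42e-6	1.97e-4	0.297	down
miR-152-3p	-1.188	10.297	20.020	7.66e-6	2.30e-4	0.439	down
miR-542-5p	-1.700	4.504	19.259	1.14e-5	3.06e-4	0.308	down
miR-655-3p	-1.516	5.976	19.235	1.16e-5	3.06e-4	0.350	down
miR-193b-3p	-1.176	7.429	17.635	2.68e-5	6.12e-4	0.443	down
miR-99a-3p	-1.082	6.079	17.541	2.81e-5	6.33e-4	0.473	down
miR-199a-5p	-1.093	14.674	17.337	3.13e-5	6.82e-4	0.469	down
miR-130a-5p	-1.780	4.420	25.248	5.04e-7	2.72e-5	0.290	down
miR-136-5p	-2.468	5.759	42.428	7.33e-11	3.30e-8	0.181	down
miR-487a-3p	-1.535	3.802	15.046	1.05e-5	9.63e-4	0.345	down
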