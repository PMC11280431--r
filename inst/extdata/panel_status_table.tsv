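mirna_id	printed_id	uaoc_direction	af_status	af_fdr	ac_status	ac_fdr	ambiguous
miR-27a-5p	miR-27a-5p	up	up	4.27e-8	up	2.84e-15	FALSE
miR-193a-5p	miR-193a-5p	up	up	1.85e-4	up	2.53e-28	FALSE
miR-5100	miR-5100	up	up	2.99e-17	up	1.57e-16	FALSE
miR-625-3p	miR-625-3p	up	up	2.55e-8	up	7.07e-7	FALSE
miR-125a-5p	miR-125a-5p	up	up	9.78e-5	up	2.58e-3	FALSE
miR-671-3p	miR-671-3p	up	up	2.23e-18	up	2.90e-12	FALSE
miR-29b-1-5p	miR-29b-1-5p	up	up	5.92e-6	up	1.70e-7	FALSE
miR-23a-5p	miR-23a-5p	up	up	8.50e-15	up	2.52e-6	FALSE
miR-200b-5p	miR-200b-5p	up	up	1.15e-7	ns	NA	FALSE
miR-92a-1-5p	miR-92a-1-5p	up	up	4.13e-8	ns	NA	FALSE
miR-2110	miR-2110	up	up	5.80e-24	ns	NA	FALSE
miR-484	miR-484	up	up	2.33e-16	ns	NA	FALSE
miR-375-3p	miR-375-3p	up	ns	NA	ns	NA	FALSE
miR-200c-3p	miR-200c-3p	up	ns	NA	ns	NA	FALSE
miR-205-5p	miR-205-5p	up	ns	NA	ns	NA	FALSE
miR-451a	miR-451a	down	down	7.16e-9	down	9.19e-27	FALSE
miR-376c-3p	miR-376c-3p	down	down	2.29e-7	down	5.65e-3	FALSE
miR-127-5p	miR-127-5p	down	down	4.96e-10	down	6.61e-3	FALSE
miR-136-3p	miR-136-3p	down	down	3.43e-3	down	3.03e-5	FALSE
miR-542-5p	miR-542-5p	down	down	1.44e-20	down	8.87e-16	FALSE
miR-193b-3p	miR-193b-3p	down	down	1.37e-9	down	1.42e-3	FALSE
miR-99a-3p	miR-99a-3p	down	down	1.88e-25	down	4.61e-35	FALSE
miR-199a-5p	miR-199a-5p	down	down	6.82e-26	down	4.95e-77	FALSE
miR-130a-5p	miR-130a-5p	down	down	6.60e-15	down	5.18e-11	FALSE
miR-4521	miR-4521	down	ns	NA	down	6.91e-10	FALSE
miR-136-5p	miR-136-5p	down	down	5.59e-5	ns	NA	FALSE
miR-495-3p	miR-495-3p	down	down	1.01e-17	ns	NA	FALSE
miR-337-3p	miR-337-3p	down	down	5.10e-13	ns	NA	FALSE
miR-98-3p	miR-98-3p	down	down	5.26e-9	ns	NA	FALSE
miR-152-3p	miR-152-3p	down	down	8.95e-3	ns	NA	FALSE
miR-655-3p	miR-655-3p	down	down	4.36e-4	ns	NA	FALSE
miR-487a-3p	miR-487a-3p	down	down	2.07e-4	ns	NA	FALSE
miR-381-3p	miR-381-3p	down	ns	NA	ns	NA	FALSE
miR-369-3p	miR-369-3p	down	ns	NA	ns	NA	FALSE
miR-539-3p	miR-6393p	down	ns	NA	ns	NA	TRUE
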