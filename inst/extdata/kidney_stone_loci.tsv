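variant_id	chromosome	position	effect_allele	other_allele	eaf	cohort_a_or	cohort_a_lo	cohort_a_hi	cohort_a_p	cohort_b_or	cohort_b_lo	cohort_b_hi	cohort_b_p	reported_meta_or	reported_meta_lo	reported_meta_hi	reported_i2
rs115239632	1	21826530	T	C	0.05	1.34	1.24	1.46	2.9e-13	1.33	1.25	1.41	1.03e-20	1.33	1.27	1.40	0.00
rs4648298	1	186641682	C	T	0.02	1.24	1.12	1.37	2.7e-5	1.26	1.14	1.39	6.16e-6	1.25	1.16	1.34	0.00
rs6753534	2	27752871	C	T	0.42	1.08	1.04	1.11	3.7e-6	1.06	1.03	1.10	9.35e-5	1.07	1.05	1.09	0.00
rs823130	1	205714372	T	C	0.44	1.06	1.03	1.09	1.8e-4	1.07	1.04	1.11	7.55e-6	1.07	1.04	1.09	0.00
rs6694088	1	220076288	T	A	0.59	1.08	1.05	1.12	7.0e-7	1.08	1.05	1.12	3.87e-7	1.08	1.06	1.11	0.00
rs838717	2	234296444	G	A	0.42	1.10	1.06	1.13	2.9e-9	1.10	1.07	1.14	8.27e-10	1.10	1.08	1.12	0.00
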