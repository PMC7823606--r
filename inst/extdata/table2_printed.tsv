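instruments	method	beta	ci95_lo	ci95_hi	ci90_lo	ci90_hi	p	ci_check
5 SNPs	ivw	0.20	-0.35	0.76	-0.26	0.67	0.473	TRUE
GRS_APN	ivw	0.20	-0.46	0.85	-0.35	0.75	0.553	TRUE
47 SNPs	ivw	0.46	0.003	0.91	0.08	0.84	0.049	FALSE
GRS_All	ivw	0.61	0.10	1.13	0.18	1.05	0.020	TRUE
16 SNPs	ivw	0.44	-0.20	1.08	-0.10	0.98	0.181	TRUE
GRS_Limited	ivw	0.57	-0.06	1.20	0.04	1.10	0.078	TRUE
5 SNPs	egger_intercept	0.06	-0.22	0.35	-0.18	0.30	0.663	TRUE
47 SNPs	egger_intercept	0.02	-0.02	0.06	-0.02	0.05	0.363	TRUE
16 SNPs	egger_intercept	0.11	0.03	0.19	0.05	0.18	0.005	TRUE
5 SNPs	weighted_median	0.12	-0.56	0.79	-0.45	0.69	0.731	TRUE
47 SNPs	weighted_median	0.14	-0.52	0.79	-0.41	0.69	0.677	TRUE
16 SNPs	weighted_median	0.12	-0.56	0.79	-0.45	0.69	0.736	TRUE
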