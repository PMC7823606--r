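snp_id	chrom	pos	effect_allele	other_allele	maf	info
rs100001	1	1000000	A	G	0.4159224173985422	NA
rs100002	1	2000000	A	G	0.42483016531914475	NA
rs100003	1	3000000	A	G	0.16445581391453745	NA
rs100004	1	4000000	A	G	0.3821790504269302	NA
rs100005	1	5000000	A	G	0.3066982075572014	NA
rs100006	1	6000000	A	G	0.2576383796520531	NA
rs100007	1	7000000	A	G	0.3446353258565068	NA
rs100008	1	8000000	A	G	0.10386663889512421	NA
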