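snp_id	effect_allele	weight	source_p	source_tier
rs100001	A	0.16565546600919134	1.715866027774423e-103	gwas_genomewide
rs100002	A	0.18774012328353704	3.976949396758268e-133	gwas_genomewide
rs100003	A	0.07546806638147457	1.3462312194840074e-13	gwas_genomewide
rs100004	A	0.11745128337755652	1.6239572410604413e-51	gwas_genomewide
rs100005	A	0.02394477394023162	0.0034857111559213425	other
rs100006	A	0.29657830898854237	4.471849015273629e-258	gwas_genomewide
rs100007	A	0.06656853377349044	5.74867959002474e-17	gwas_genomewide
rs100008	A	0.17143172906555273	1.5091469446976795e-43	gwas_genomewide
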