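# Per-temporal-group summary of the published human PPI study
# group	age_mya	n_genome	n_network	mean_degree	mean_clustering	mean_omega
1	990	720	544	29.509	0.212	0.034
2	450	5211	3546	17.399	0.196	0.089
3	360	1929	1093	13.100	0.193	0.096
4	310	2694	1348	10.061	0.180	0.128
5	90	6663	2794	8.623	0.169	0.179
6	50	1313	205	3.434	0.176	0.168
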