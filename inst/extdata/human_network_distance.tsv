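# Average network distances between temporal groups (published human PPI study)
	TG1	TG2	TG3	TG4	TG5	TG6
TG1	3.611	3.771	3.835	3.931	4.035	4.183
TG2	3.771	3.922	3.986	4.078	4.181	4.325
TG3	3.835	3.986	4.044	4.138	4.239	4.387
TG4	3.931	4.078	4.138	4.227	4.322	4.463
TG5	4.035	4.181	4.239	4.322	4.404	4.538
TG6	4.183	4.325	4.387	4.463	4.538	4.655
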