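# Average functional distances between temporal groups (published human PPI study)
	TG1	TG2	TG3	TG4	TG5	TG6
TG1	4.413	4.560	5.344	6.109	6.512	6.018
TG2	4.560	4.321	5.054	5.643	6.070	6.311
TG3	5.344	5.054	4.996	5.900	6.189	5.595
TG4	6.109	5.643	5.900	5.921	5.938	4.967
TG5	6.512	6.070	6.189	5.938	4.903	4.377
TG6	6.018	6.311	5.595	4.967	4.377	2.975
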