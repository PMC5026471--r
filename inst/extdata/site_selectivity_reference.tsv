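state	system	site	ddg	err
wildtype	E1_S0	I	0.1	0.1
wildtype	E1_S0	II	4.5	0.1
wildtype	E1_S0	III	1.8	0.1
wildtype	E1_S1	I	3.7	0.2
wildtype	E1_S1	II	1.7	0.1
wildtype	E1_S1	III	4.7	0.1
wildtype	E1_S2	I	-3.5	1.0
wildtype	E1_S2	II	3.8	0.3
wildtype	E1_S2	III	2.9	0.6
wildtype	E1_S3	I	-1.5	0.2
wildtype	E1_S3	II	4.7	0.4
wildtype	E1_S3	III	-0.5	0.3
wildtype	E2_S0	I	-4.4	0.3
wildtype	E2_S0	II	-6.1	0.0
wildtype	E2_S1	I	-3.5	0.1
wildtype	E2_S1	II	-6.1	0.1
wildtype	P-E2_S0	I	-1.0	0.6
wildtype	P-E2_S0	II	0.7	0.4
mutant	E1_S1M	I	1.4	0.1
mutant	E1_S1M	II	5.7	0.0
mutant	E1_S1M	III	2.4	0.1
mutant	E1_S2M	I	4.3	0.7
mutant	E1_S2M	II	6.6	0.6
mutant	E1_S2M	III	5.2	0.9
mutant	E1_S3M	I	-0.6	0.1
mutant	E1_S3M	II	1.7	0.1
mutant	E1_S3M	III	0.0	0.0
mutant	E2_S1M	I	-3.3	0.3
mutant	E2_S1M	II	-5.7	0.0
mutant	E2_S2M	I	-5.4	0.1
mutant	E2_S2M	II	-6.4	0.1
mutant	E2_S3M	I	-3.8	0.1
mutant	E2_S3M	II	-7.2	0.1
mutant	P-E2_S1M	I	0.8	0.9
mutant	P-E2_S1M	II	1.9	0.4
mutant	P-E2_S2M	I	1.6	0.5
mutant	P-E2_S2M	II	1.9	0.4
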