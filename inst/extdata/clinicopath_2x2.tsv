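feature	category	high	low
age	>45	9	6
age	<=45	2	3
lymph_node_metastasis	yes	6	2
lymph_node_metastasis	no	3	9
ER	positive	9	3
ER	negative	2	6
PR	positive	7	3
PR	negative	4	6
HER2	positive	12	2
HER2	negative	2	4
TNM_stage	T1/T2	5	9
TNM_stage	T3/T4	5	1
Ki-67	<=10%	2	4
Ki-67	>10%	11	3
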