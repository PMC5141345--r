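group	count
amplified_gsr_pos	7
amplified_gsr_neg	5
neutral_gsr_pos	3
neutral_gsr_neg	15
mutant_gsr_pos	0
mutant_gsr_neg	6
wildtype_gsr_pos	10
wildtype_gsr_neg	14
crpc_gsr_pos	12
crpc_gsr_neg	24
naive_gsr_pos	0
naive_gsr_neg	21
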