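variable	level	n_high_pos	n_high_neg	n_low_pos	n_low_neg
pathological_type	serous	480	24	449	55
figo_stage	III-IV	615	62	580	100
pathological_grade	high	548	149	493	194
platinum_response	sensitive	601	79	582	79
tp53_status	mutated	231	7	225	8
macroscopic_disease	yes	457	216	442	230
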