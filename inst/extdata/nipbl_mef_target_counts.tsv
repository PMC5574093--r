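direction	total	gene_region	promoter	gene_body	downstream	none
up	62	30	14	22	6	32
down	156	85	47	61	14	71
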