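file	checksum
site_selectivity_reference.tsv	0979694063
boosting_parameters_reference.tsv	0665689043
pka_cycle_inputs.tsv	0467083635
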