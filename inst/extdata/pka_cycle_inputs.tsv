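parameter	value	unit
dg_site_deprot	-44.8	kcal/mol
dg_bulk_deprot	-51.9	kcal/mol
reference_pka	4.1	pK
temperature	303.15	K
dg_bulk_na_to_k	18.34	kcal/mol
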