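variable	estimate	std_error	category
AAT	-0.03925	0.008156	climate
sand	-0.05083	0.012719	soil_physical
clay	-0.04031	0.015062	soil_physical
pH	-0.03542	0.010842	soil_chemical
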