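quantity	numerator	denominator
dark_deg	916	6918
array_dark	4210	19441
evidence_covered	701	916
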