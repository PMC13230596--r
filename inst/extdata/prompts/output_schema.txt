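Return the result as a JSON array, one object per experiment, with
exactly these keys: protein_name, protein_conc, rna_conc, ph,
temperature, phase_status, sequence_region, modification_state. Use null
for any condition not determinable. Output the JSON array only, no
commentary.
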