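You are given material from a research article on liquid-liquid phase
separation (LLPS). Identify every individual LLPS experiment reported and
extract, for each one: the protein name, the protein concentration, the
RNA concentration, the buffer pH, the temperature, and the phase status
(whether phase separation was observed). Also note the protein sequence
region and any modification state when stated. Report one entry per
experimental condition; do not merge distinct conditions.
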