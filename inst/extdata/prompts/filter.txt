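Only include experiments meeting all of the following criteria. The
experiment directly observes liquid-liquid phase separation. It uses a
single type of protein and a single type of RNA (a fusion protein counts
as one type). Only protein, RNA, pH, salt, or temperature are varied, and
the outcome is shown in a microscopy image or a scatter plot. Every
condition to be extracted is stated or clearly implied in the paper.
Exclude all other experiments.
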