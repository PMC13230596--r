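Domain knowledge. LLPS experiments test whether a protein, often together
with RNA, demixes into condensed droplets under given solution conditions.
In microscopy panels, round droplets on a dark or uniform background
indicate phase separation; a homogeneous field indicates a single mixed
phase. In phase-diagram scatter plots, each point is one experiment: its
coordinates give the protein and RNA concentrations and the marker style
distinguishes separated from non-separated outcomes. Concentrations are
typically reported in molar units (nM, uM, mM) or as mass per volume
(mg/mL). Temperature may be given as a number or as "room temperature".
The same protein may appear under different names or abbreviations; use
the name as written. Sequence regions (e.g. an IDR or RGG domain) and
modifications (e.g. phosphorylation) qualify which protein construct was
used.
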