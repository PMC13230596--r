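# Default normalization rules. Any omitted section falls back to the
# package defaults; the protein synonym map is corpus-specific and ships
# empty — supply your own canonical dictionary here.
temperature_aliases:
  rt: 25
  r.t.: 25
  room temperature: 25
  room temp: 25
  ambient: 25
molar_unit_factors:
  M: 1.0e6
  mM: 1.0e3
  uM: 1
  nM: 1.0e-3
  pM: 1.0e-6
non_convertible_units:
  - mg/ml
  - ug/ml
  - ng/ul
  - ng/ml
  - g/l
  - "%"
  - "%w/v"
  - wt%
protein_synonyms: {}
phase_vocab:
  droplet: 1
  droplets: 1
  llps: 1
  condensate: 1
  condensates: 1
  phase separation: 1
  phase separated: 1
  phase-separated: 1
  two-phase: 1
  two phase: 1
  two phases: 1
  demixed: 1
  ps: 1
  "yes": 1
  "1": 1
  soluble: 0
  one phase: 0
  one-phase: 0
  single phase: 0
  no llps: 0
  no phase separation: 0
  homogeneous: 0
  mixed: 0
  dilute: 0
  "no": 0
  "0": 0
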