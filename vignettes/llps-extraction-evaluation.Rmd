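---
title: "Scoring LLPS experiment extraction: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring LLPS experiment extraction: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(llpsie)
```

## The problem

Liquid–liquid phase separation (LLPS) experiments test whether a
protein, often with RNA, demixes into condensed droplets under given
solution conditions. The literature reports these experiments almost
entirely through figures — phase-diagram scatter plots where every
point is one experiment, and micrographs where droplet morphology is
the outcome — with the conditions split between axis labels, captions
and the methods text. A multimodal extraction system turns this
material into tabular records; `llpsie` supplies the surrounding
machinery (record types, normalization, prompt composition, a pipeline
with a pluggable model backend) and, centrally, an evaluator that
scores an extracted record set against curated labels.

Six conditions are scored per experiment: protein name, protein
concentration, RNA concentration, buffer pH, temperature and the
binary phase status. Sequence region and modification state are
carried as auxiliary annotations for protein identification but are
not scored.

## The evaluation model

The hard part of scoring is that extracted records arrive in arbitrary
order, with noisy values, omissions and spurious entries, so record
identity must be *recovered* before per-field correctness can be
judged. The evaluator treats this as an assignment problem within each
scope — a figure for figure-by-figure extraction, a whole paper for
single-shot extraction.

**Distances.** For numeric fields the distance between an extracted
value $x_{pred}$ and a label value $x_{true}$ is
$|x_{pred}-x_{true}| / (x_{max}-x_{min})$, where the range is the
minimum and maximum of the *label* data for that field in the
evaluated scope. Normalizing by the label range makes 0.1 µM errors
matter on a 0–1 µM sweep and not on a 0–100 µM sweep, which matches
how a curator would judge a read-off-the-axis error. Values outside
the label range are clamped to distance 1 so the record cost stays a
mean of unit-interval terms. A degenerate range (all labels equal,
common for per-figure pH and temperature) falls back to exact-match
semantics: 0 if equal, else 1. Text fields use one minus the gestalt
(Ratcliff–Obershelp) similarity $2M/(|a|+|b|)$, where $M$ totals the
matching blocks found recursively around longest common substrings;
ties for the longest block resolve to the earliest position in the
first string, then in the second, matching the reference
sequence-matcher implementations. Phase status is a 0/1 mismatch
indicator.

**Record cost and matching.** The cost of pairing two records is the
arithmetic mean of the six per-field distances. Two conventions are
needed where the formulae are silent. A field missing on both sides
contributes 0 (agreeing absence is not an error); a field missing on
exactly one side contributes 1 (an omission or an invention is
maximally wrong). Non-convertible quantities ("2 mg/mL") compare
numerically only when both units match exactly after case folding;
otherwise the distance is 1, because comparing mg/mL against µM
numerically is meaningless without a molecular weight. The full
extracted-by-label cost matrix is solved as a minimum-cost assignment
with the Hungarian method (the O(n³) potentials / shortest augmenting
path form, implemented in the package); rectangular matrices are
solved directly, producing min(|E|,|L|) pairs with the leftover side
reported unmatched. Augmenting rows in index order with
lowest-column-first scanning makes tie resolution deterministic across
platforms.

**Classification and aggregation.** At threshold $\tau$ (default 0.2,
deliberately tolerant of curation noise in hand-labelled data), a
matched field with distance strictly below $\tau$ is a true positive,
otherwise a false positive; unmatched extracted records are false
positives and unmatched labels false negatives in each present field.
Note the asymmetry: a matched-but-wrong field counts against precision
only. An optional strict-recall mode additionally counts it (and
label fields the extraction left missing) as false negatives; it is
off by default, keeping the headline metrics those of the plain rules.
The comparison is configurable to $\le$ for sensitivity checks — at
$\tau = 0$ the strict rule scores nothing at all, so a "fully
rigorous" threshold is only meaningful with $\le$, where it demands
exact field agreement. Precision, recall and F1 are computed per field
and scope; zero-denominator metrics are left undefined and *excluded*
from aggregation rather than imputed as 0, and the exclusion is
visible in the outputs. Across scopes, each field gets a mean and SD,
and the overall Average is the mean of the six per-field means, with
its SD taken across scopes of the per-scope average (the per-scope
average being the mean of that scope's defined per-field values).

**Method comparison.** Two runs over the same scopes are compared by a
paired Wilcoxon signed-rank test on per-scope average F1. Zero
differences are dropped (the Wilcoxon convention). The p-value comes
from the exact sign-flip distribution of the signed-rank statistic,
enumerated by convolution over midranks, so tied differences — e.g. a
constant shift — are handled exactly rather than by a normal
approximation; the flag is significance at p < 0.05.

## Normalization

Extracted values are standardized before evaluation. Temperatures are
converted to °C, with the room-temperature aliases ("RT", "r.t.",
"room temperature", "ambient") collapsed to 25 °C; Kelvin and
Fahrenheit inputs are also parsed — a harmless superset controlled by
the rules table, since sources occasionally report 310 K. Molar
concentrations rescale to µM; mass-per-volume units pass through
unchanged and flagged non-convertible. Protein names are casefolded,
whitespace-collapsed, and mapped through a synonym table that ships
*empty*: canonical protein dictionaries are corpus-specific
configuration, not package policy. Phase descriptions map through a
small binary vocabulary ("droplets", "two-phase" → 1; "soluble",
"one phase" → 0); unmapped tokens are an error rather than a guess,
because phase status is strictly binary. A leading "pH" token is
stripped from pH strings. `normalize_record()` collects per-field
failures instead of failing the record, and is idempotent — canonical
values pass through — which is what lets the pipeline re-normalize
defensively at no cost.

## What the synthetic generator emulates

`generate_labels()` produces per-figure label sets with the structure
of real LLPS figures: a contiguous protein-by-RNA concentration
sub-grid (log-spaced stock-dilution style values), one buffer pH and
one temperature per figure, and a phase boundary that is monotone in
the concentration product, with the cutoff at the median product so
both outcomes occur. Defaults — 49 figures grouped about three per
paper, grids of 3–6 by 3–5 levels giving a mean of 18 experiments per
figure and roughly 880 records in total — mirror the scale of the
curated benchmark this tooling targets. `corrupt()` then applies the
error modes observed in practice: dropped records, missed fields,
small Gaussian read-off noise on concentrations (SD as a fraction of
the figure's label range, default 0.01), single-character name typos,
re-expression of µM values in mM/nM before normalization, and spurious
records.

The generator's defining feature is that expected TP/FP/FN tallies are
computed *during* corruption by replaying the evaluator's own distance
and threshold rules on the known true correspondence — making the
headline test exact, not approximate. That requires the optimal
assignment to recover the true correspondence, which is enforced by
construction and rejection:

* each surviving record's cost to its true label must be a strict row
  minimum; exact ties are accepted only when tie-equivalent (identical
  per-field distance vectors, as when grid rows differ only in a field
  the record lost), in which case every optimal assignment yields the
  same tallies;
* spurious records carry only name and concentrations, with values
  past the label range (distance clamps to 1) and a name at gestalt
  distance ≥ 0.5 from the figure's protein, making their cost rows
  constant — so whichever leftover label they absorb, the tallies are
  unchanged — and requiring a margin (default 0.02 worth of headroom,
  parameter `margin = 0.005`) below every spurious row for all
  survivors;
* a corruption draw violating these conditions is redrawn (counted in
  the manifest); a record that loses all six fields is reclassified as
  a drop, since an all-missing record is not a valid record.

When drops and spurious insertions co-occur, the matching fills
dropped labels with spurious records (their fields were never
recoverable, so they contribute false positives either way), and
per-field false negatives equal max(drops − spurious, 0). Scenarios
are pure functions of their configurations and seeds.

What the generator does **not** emulate: real figure images (scenarios
are record-level; the mock backend replays the raw textual forms a
model would emit), multi-protein complexes, correlated error modes
(e.g. a systematically misread axis shifting every point), free-text
phase descriptions beyond the vocabulary, and label sets with missing
fields — generated labels are complete, as curated ground truth
typically is. Passing the synthetic suite therefore demonstrates that
the *scoring machinery* is exact under realistic record structure; it
says nothing about any particular model's extraction quality on real
figures.

## Numerical and interface choices

* Serialized tables use shortest-round-trip decimal formatting, so
  write → read is the identity and write → read → write is
  byte-identical; unit jitter in mock scripts is applied only when the
  mM/nM factor round-trips exactly in double arithmetic.
* The assignment solver is validated against an exhaustive-permutation
  oracle for all shapes up to 7×7; tie-breaking is deterministic.
* Empty sides short-circuit: an empty extraction scores all labels as
  false negatives without building a matrix, and vice versa.
* Scopes present in the labels but absent from an extraction evaluate
  against an empty extraction (a normal pipeline outcome); the CLI
  treats the reverse — extracted scopes unknown to the labels — as a
  validation error listing the orphans.
* Matching is threshold-independent, so threshold sweeps match once
  per scope and re-classify per threshold.
* Model output parsing is total: the first balanced JSON array is
  extracted (code fences stripped, string-aware bracket scan), unknown
  keys are ignored and logged, objects with none of the six fields are
  skipped, and prose-only responses yield an empty, annotated record
  set. Requesting structured JSON output from the model is this
  package's choice for making post-processing deterministic.
* Backend adapters are plain functions from call to response; only
  transport errors are retried (3 times), never model-content errors,
  for reproducibility. The deterministic mocks (canned responses, or
  oracle mode replaying a scenario) are the tested backends.

Test and acceptance problem sizes are the package's own choices: the
tally-recovery check uses 100 two-figure scenarios spanning corruption
rates 0, 0.05 and 0.2; the assignment oracle uses 200 random matrices
up to 7×7; the end-to-end determinism check runs a three-figure
scenario through all four prompt variants twice.

## Known limitations

* The six-field record cost always averages six terms; an alternative
  (averaging only fields present in the label) would change costs for
  sparse labels. The six-field convention is reported in the output
  metadata.
* Matched-pair misses not counting as false negatives means recall can
  look generous when a model extracts a record but garbles a field;
  strict-recall mode exists for exactly that sensitivity analysis.
* Casefolding unknown protein names means a typo'd name is compared in
  folded form; with the default empty synonym map, short names a
  single edit away can still exceed the 0.2 threshold (distance 1/len
  under the gestalt ratio for a substitution).
* The Hungarian implementation is pure R; it is comfortably fast for
  per-figure matching (tens of records) but not tuned for record sets
  orders of magnitude larger.
* Live MLLM adapters are intentionally out of the test surface; the
  backend contract is one function, and anything honouring it works in
  the pipeline.
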