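---
title: "An integrated germline–tumor decision tree for MMR VUS in suspected Lynch syndrome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An integrated germline–tumor decision tree for MMR VUS in suspected Lynch syndrome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lynchtree)
```

## The model

A variant of uncertain significance (VUS) in a mismatch-repair (MMR) gene
leaves the question of Lynch syndrome open. If the variant really is
inactivating, the patient's tumor should say so: the wild-type allele is
typically lost somatically (the second hit), the tumor becomes MMR-deficient
and therefore microsatellite-unstable (MSI-high), and immunohistochemistry
(IHC) loses the protein — together with its heterodimer partner, because the
MMR proteins work as MLH1–PMS2 and MSH2–MSH6 dimers. Two sporadic mimics
must be excluded before that signature can be credited to the germline:
*MLH1* promoter hypermethylation (which definitionally marks sporadic
MMR-deficient tumors of both organ types) and, in colorectal cancer only,
somatic *BRAF* p.V600E (present in roughly half of sporadic MMR-deficient
colorectal cancers and essentially absent in Lynch tumors; BRAF is not
informative in endometrial cancer and is never consulted there).

`lynchtree` encodes this reasoning as a two-stage rule tree over a
single-case evidence bundle (`evidence_case()`).

**Stage 1 — structural gates.** Five requirements are checked exhaustively
and *all* failures are reported as family-`I` flag codes in an
`INCONCLUSIVE` verdict:

1. exactly one germline MMR VUS, no additional pathogenic germline MMR
   alteration, no *EPCAM* 3′ deletion (`CRC I-I` / `EC I-I`);
2. clinical criteria: PREMM5 ≥ 2.5 % (inclusive) **or** Amsterdam II
   (`I-II`);
3. a documented somatic second hit in the queried gene (`CRC I-V` /
   `EC I-IV`);
4. MSI-high (`CRC I-VI` / `EC I-V`);
5. an assessable IHC panel showing loss of at least one protein
   (`CRC I-VII` / `EC I-VI`).

The sporadic-etiology check is deliberately *not* a structural gate, because
its consequence depends on the queried gene (stage 2). Reporting every
failing gate at once mirrors how the published control cases carry multiple
flag codes, and gives the user a complete worklist rather than the first
failure.

**Stage 2 — per-gene verdict.** With all gates passed, the canonical IHC
pattern and the sporadic check decide:

* ***MLH1***: methylation-positive, BRAF-positive, or both tests unavailable
  → `NEUTRAL` (the tumor may simply be sporadic; the VUS stays uncertain).
  With sporadic etiology excluded, MLH1+PMS2 loss (with or without secondary
  MSH6 loss) or isolated PMS2 loss → `POSITIVE`; isolated MLH1 loss is a
  recognized but unusual pattern → `NEUTRAL`.
* ***PMS2***: MLH1+PMS2 co-loss suggests the defect is actually in *MLH1*,
  so it is `NEUTRAL` regardless of the sporadic tests. Isolated PMS2 loss is
  `POSITIVE` when sporadic etiology is excluded and `INCONCLUSIVE` (with the
  BRAF/methylation flag code) otherwise.
* ***MSH2*** and ***MSH6***: a non-excluded sporadic check refuses the
  assessment outright (`INCONCLUSIVE` with the corresponding flag code).
  Otherwise MSH2+MSH6 loss or isolated MSH6 loss is `POSITIVE` for an
  *MSH2* VUS; isolated MSH6 loss is `POSITIVE` for an *MSH6* VUS; isolated
  MSH2 loss, all-four loss (*MSH2*), MSH2+MSH6 loss (*MSH6*, pointing at
  *MSH2*) and MSH6+MLH1+PMS2 loss (*MSH6*, secondary loss) are `NEUTRAL`.

Any combination not enumerated above is `OUT_OF_SCOPE`: the tree refuses to
guess rather than extrapolate.

For colorectal cases, a negative BRAF result with methylation untested is
accepted as excluding sporadic etiology. The per-gene sections of the source
material state this explicitly only for *MLH1*, but most of the
colorectal positive controls carry exactly that configuration
(BRAF negative, methylation not tested) with `POSITIVE`-family printed
codes, so the package applies it uniformly across genes.

### Evidence codes

Codes are strings like `CRC I-II` or `EC V-I`: family `I` flags absent or
adverse key evidence; families `II`–`V` carry the POSITIVE/NEUTRAL scenarios
for *MLH1*, *PMS2*, *MSH2* and *MSH6* respectively. Family membership and
the verdict category are the semantically meaningful parts. Sub-indices
within families `II`–`V` are assigned by this package's own deterministic
enumeration over (sporadic-marker configuration × IHC pattern); the
scenario-level supplementary tables that would fix a canonical sub-index
numbering are not distributed with the source publication, and the code IDs
printed in its control tables cannot all be reconciled with the in-text code
citations under any single mapping. The packaged control table therefore
retains the printed codes verbatim as provenance (`printed_code`) but the
evaluation harness compares categories, never sub-indices.

## Clinical-criteria evaluators

**PREMM5.** The published PREMM5 model returns a percent probability of
carrying an MMR mutation; computing it is out of scope — the score is an
input. The threshold is 2.5 % and *inclusive*: a score of exactly 2.50 % was
assessed `POSITIVE` in the control cohort, and "≥ 2.5 %" is the stated
acceptance rule. An absent score never meets the threshold. The threshold is
configurable (`run_config()`), defaulting to 2.5.

**Amsterdam II.** `amsterdam_ii_met()` evaluates pedigrees against the four
clauses: at least three relatives affected by a Lynch-associated cancer
(default label set: colorectal, endometrial, small bowel, ureter, renal
pelvis — configurable); one of them a first-degree relative of two others;
two successive generations affected; one diagnosis before age 50 (strictly —
a diagnosis at exactly 50 fails); and, when colorectal cancer is among the
qualifying diagnoses, familial adenomatous polyposis excluded. Design
choices the criteria text leaves open, decided here once:

* *The proband counts as a relative* (configurable via `include_proband`):
  the clause list speaks of the family including the index patient.
* *"Successive generations"* is read literally: the affected set's
  generation indices must contain two values differing by exactly one.
* *Degree of relationship* is the shortest path through parent links, with
  full siblings (both parents shared) joined directly at degree 1; the
  sibling shortcut composes, so an aunt/uncle through a full sibling is
  degree 2 and a half-sibling is degree 2. This matches standard genetic
  convention for the first- and second-degree relationships the criteria
  use. A consequence of the path-based definition is that relatives by
  marriage can receive a finite degree through shared descendants; since
  only degree 1 enters Amsterdam II, this does not affect the evaluation.
* The subset search is exhaustive over affected members — pedigrees are
  small, and exhaustiveness makes the monotonicity property (adding an
  affected first-degree relative can never un-meet the criteria) immediate.

At the case level the two criteria combine as a simple disjunction
(`clinical_criteria_met()`); an `UNKNOWN` Amsterdam flag counts as not met,
so missing family history can be compensated by the PREMM5 score but never
silently satisfied.

## Questionnaire

The published interface asks 11 radio-button questions for colorectal and 10
for endometrial cancer, the difference being exactly the BRAF question; the
wording is not printed, so the schemas here are reconstructed from the
evidence classes the tree consumes: VUS count, gene, other pathogenic
alteration, EPCAM deletion, PREMM5 threshold (yes/no — a radio button cannot
carry a numeric score; the batch interface accepts the numeric score
instead), Amsterdam II (met / not met / unknown), BRAF (CRC only),
methylation, second hit, MSI, and the canonical IHC pattern (11 labels, one
per pattern plus a not-assessable option). `answers_to_case()` maps answers
deterministically onto a case — the PREMM5 "yes" maps to a score exactly at
the threshold, "no" to an absent score — and `case_to_answers()` inverts it,
so answer sets round-trip exactly.

The full answer space is finite: 114,048 colorectal and 38,016 endometrial
combinations. `assess_answer_space()` assesses every combination (about
20 s for the colorectal space on one CPU), which lets the test suite verify
engine properties by brute force instead of sampling.

## Properties verified by exhaustive enumeration

Over both complete answer spaces the suite confirms:

* **totality/determinism** — every combination yields exactly one
  well-formed verdict, never an internal error;
* **conjunction** — for every `POSITIVE` combination, flipping any single
  required evidence to its absent/adverse value (clinical criteria
  withdrawn, MSI→MSS, second hit removed, methylation→positive, IHC→no
  loss) makes it non-`POSITIVE`;
* **methylation veto** — no methylation-positive combination is ever
  `POSITIVE`, for any gene;
* **EC/BRAF independence** — endometrial verdicts are bit-identical under
  every value of the BRAF field;
* **monotonicity of ignorance** — hiding a *non-adverse* tested result
  (a negative BRAF or methylation result, or any MSI result, set to
  not-tested) never converts a non-`POSITIVE` combination into `POSITIVE`.

The restriction in the last property is deliberate and worth stating
plainly: the rule set itself is *not* monotone when an adverse sporadic
marker is hidden. For a colorectal case, "methylation negative **or** BRAF
negative" excludes sporadic etiology, so a tumor with a positive methylation
result and a negative BRAF result is blocked — but the same case with the
methylation result withheld would pass on BRAF alone. This
information-hiding hazard is inherent to accepting a single negative
sporadic marker; it is a property of the published rule logic, not of this
implementation, and users should regard the methylation field as mandatory
reporting whenever the test was performed.

## The packaged control cohort

`inst/extdata/positive_controls.tsv` transcribes the 52 positive-control
cases (patients with Lynch-related CRC/EC and *known pathogenic* MMR
variants) from the source publication's two control tables: PREMM score,
germline variant, BRAF/methylation results, MSI, IHC, somatic second hit,
and the printed code. Points a transcriber must decide, decided here once:

* **Cancer-type assignment.** The two printed table captions conflict with
  the per-subject organ labels and with the in-text group counts. Subjects
  1–29 are taken as colorectal and 30–52 as endometrial, because only the
  1–29 table carries a BRAF column and BRAF is explicitly not a component
  for endometrial cancer, and because the flag codes printed for subjects
  25 (methylation) and 43 (MSI) fit the CRC/EC code numbering only under
  this assignment. The per-subject organ labels from the demographics table
  are retained as free-text provenance (`reported_organ`).
* **Somatic `inactivating` flags** are the table's own per-row assertions,
  not re-derived annotations: truncating, frameshift, canonical-splice,
  copy-loss and structural events are inactivating; the three events in
  rows the table itself flags for absent biallelic inactivation (a missense,
  an intronic +5 change, an in-frame deletion) are not; conversely three
  non-truncating events printed with `POSITIVE`-family codes are. Under
  this transcription the cohort's fifteen "no second hit" flags reproduce
  exactly.
* PREMM decorations are normalized (`2.50%`→2.5, `>50%`→50, `[9.7%]`→9.7),
  as are result strings (`Neg`/`Unmethylated`→negative, `N/A`/`None`→not
  tested, `MSI-S`→MSS, `hypermethylation`→positive).

`evaluate_controls()` assesses all 52 records (well under a second) and
reproduces the published split — 23 `POSITIVE`, 29 non-`POSITIVE`, zero
mismatches — with flag-code tallies of 15 (second hit absent), 8 (PREMM
below threshold), 4 (MSI absent/stable) and 5 (IHC normal or not
assessable). The source text tallies the last group as 4; its own tables
mark five rows as IHC-limited (three normal-IHC rows plus two
partial/equivocal rows), and no single grouping reconciles all four printed
tallies, so the harness reports its own counts and asserts only the
category split.

What these controls do and do not show: they are pathogenic variants
re-entered as if they were VUS, so they validate that the tree recovers
known-positive signatures and flags incomplete ones. They cannot measure
specificity (no benign-variant controls are printed), and the cohort-scale
statistics of the original 5000-patient screen require institutional data
that is deliberately out of scope here.

## Numerical and degenerate-input choices

* Thresholds compare with `>=` (inclusive) on plain doubles; scores are
  percentages in [0, 100], validated.
* HGVS strings are opaque identifiers, checked only for non-emptiness; no
  variant normalization or transcript mapping.
* An IHC panel with any equivocal, partial or unperformed stain is
  `NOT_ASSESSABLE` and fails the IHC gate — partial patterns are never
  interpreted.
* A case with every tumor field untested is simply `INCONCLUSIVE` with all
  gate codes; validation errors are reserved for structurally invalid input
  (unknown labels, empty cDNA), which `assess_case()` refuses with the full
  violation list.
* `COPY_LOSS` somatic events count as inactivating regardless of the
  annotator flag (a lost copy cannot be benign); cis/trans phase is not
  modeled — a qualifying somatic event is presumed in trans.
* Random case generation (`generate_random_cases()`) restores the RNG state
  and is fully determined by its seed.

## The synthetic answer-space generator

`enumerate_answer_space()` emulates every entry a questionnaire user could
make; it is exhaustive, so property tests have no sampling gaps. What it
does *not* emulate: free-text cDNA variation (a fixed placeholder is used —
the engine treats cDNA as opaque), numeric PREMM scores away from the
threshold boundary (the questionnaire layer is binary by design; numeric
scores are exercised by the control cohort and unit tests), and somatic
event lists (the questionnaire asserts the second hit as a yes/no override).
Passing properties on this space therefore certify the decision logic, not
the handling of free-text inputs, which is intentionally trivial.

## Known limitations

* Sub-index numbering inside code families `II`–`V` is package-defined
  (family membership is authoritative; sub-indices are reproducible but not
  comparable to the source's supplementary numbering).
* The adverse-marker information-hiding hazard described above.
* Only CRC and EC are supported; other Lynch-associated tumors are
  `OUT_OF_SCOPE` by construction.
* The Amsterdam II evaluator needs explicit generations and parent links;
  free-text family histories (as printed in the demographics table of the
  control cohort) are not parsed.

```{r cohort}
s <- evaluate_controls(load_control_table())
s$positive
s$non_positive
nrow(s$mismatches)
s$per_code
```
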