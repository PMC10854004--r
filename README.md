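# lynchtree

Integrated germline + tumor evidence assessment of mismatch-repair (MMR)
variants of uncertain significance (VUS) in suspected Lynch syndrome.

## The problem

Lynch syndrome is caused by heterozygous inactivating germline alterations in
the MMR genes *MLH1*, *MSH2*, *MSH6* and *PMS2* (or an *EPCAM* 3′ deletion).
Standard germline classification does not consult the tumor, yet the tumor of
a true Lynch patient carries a characteristic molecular signature: somatic
inactivation of the remaining wild-type allele (the "second hit"),
microsatellite instability (MSI-high), and loss of the corresponding MMR
protein(s) on immunohistochemistry (IHC), with sporadic mimics excluded by
*BRAF* p.V600E (colorectal only) and *MLH1* promoter methylation testing.

`lynchtree` implements a conservative rule-based decision tree that
integrates those evidence classes for a single germline MMR VUS in a
Lynch-related colorectal (CRC) or endometrial (EC) cancer patient and renders
one of four verdicts:

| Verdict | Meaning |
|---|---|
| `POSITIVE` | every required evidence is present and the pattern supports relevance of the VUS to Lynch syndrome |
| `NEUTRAL` | evidence complete but the pattern is unusual or rare; significance stays uncertain |
| `INCONCLUSIVE` | one or more key evidence absent or adverse; assessment refused, with one flag code per failing requirement |
| `OUT_OF_SCOPE` | the combination falls outside the current parameters of the algorithm |

The decision tree requires, in order: exactly one germline MMR VUS (no other
pathogenic MMR alteration, no *EPCAM* 3′ deletion); clinical criteria
(PREMM5 score ≥ 2.5 %, inclusive, **or** Amsterdam II); a documented somatic
second hit in the queried gene; MSI-high; and an assessable IHC panel with
loss of at least one MMR protein. The sporadic-etiology check
(BRAF/methylation) is then routed per gene: for *MLH1* an adverse or missing
result is `NEUTRAL`; for *MSH2*/*MSH6* it is `INCONCLUSIVE`; for *PMS2*,
combined MLH1+PMS2 loss is `NEUTRAL` regardless of it. Verdict codes are
grouped in families: `I` = missing-evidence flags, `II`–`V` = per-gene
scenarios for *MLH1*, *PMS2*, *MSH2*, *MSH6*.

The package also provides the two questionnaire schemas (11 radio-button
questions for CRC, 10 for EC — the EC schema omits BRAF), a pedigree-based
Amsterdam II evaluator, a ClinVar submission-synopsis exporter, a packaged
52-case positive-control table with an evaluation harness, exhaustive
answer-space enumeration for property testing, and a CLI.

## Worked example

```r
library(lynchtree)

case <- evidence_case(
  cancer_type = "CRC",
  queried_variant = germline_finding("MSH2", "c.226C>T", "p.Q76*"),
  clinical = clinical_evidence(premm5_percent = 6.7),
  tumor = tumor_profile(
    braf_v600e = "NEGATIVE",
    mlh1_promoter_methylation = "NEGATIVE",
    msi = "MSI_HIGH",
    somatic_events = list(
      somatic_event("MSH2", "c.2334C>A (p.C778*)", inactivating = TRUE))),
  ihc = ihc_panel(mlh1 = "INTACT", msh2 = "LOST", msh6 = "LOST",
                  pms2 = "INTACT"))

assess_case(case)
#> <verdict> POSITIVE [CRC IV-I]
#>   POSITIVE assessment for the MSH2 c.226C>T germline variant in colorectal
#>   cancer [CRC IV-I]: loss of MSH2 and MSH6 in tumor nuclei is compatible
#>   with biallelic MSH2 inactivation and degradation of its dimerization
#>   partner.
```

The verdict is `POSITIVE` with the single family-IV code (`IV` = *MSH2*
scenarios): the PREMM5 score passes the 2.5 % threshold, a truncating somatic
*MSH2* allele documents biallelic inactivation, the tumor is MSI-high, BRAF
is negative, and the MSH2+MSH6 co-loss on IHC is exactly the pattern
biallelic *MSH2* inactivation produces. Remove any one of those evidences and
the verdict drops out of `POSITIVE` — e.g. with `premm5_percent = 1.3` the
result is `INCONCLUSIVE` with flag code `CRC I-II` (clinical criteria not
met).

Running the packaged positive-control cohort:

```r
s <- evaluate_controls(load_control_table())
c(s$positive, s$non_positive)
#> [1] 23 29
nrow(s$mismatches)
#> [1] 0
```

All 52 pathogenic-variant control cases are classified as expected: the 23
with complete evidence are `POSITIVE`, and the 29 with absent or unusual
evidence are flagged rather than called, reflecting the deliberately
conservative logic.

### Command line

```sh
inst/cli/lynchtree assess --cancer-type CRC --gene MSH2 --cdna "c.226C>T" \
    --premm5 6.7 --braf NEGATIVE --methylation NEGATIVE --second-hit yes \
    --msi MSI_HIGH --ihc MSH2_MSH6_LOSS
inst/cli/lynchtree evaluate-controls
inst/cli/lynchtree schema --cancer-type=crc
inst/cli/lynchtree batch cases.tsv --out=verdicts.tsv
inst/cli/lynchtree export-clinvar ... --dir out/ --date 2024-01-24
```

## Scope

The PREMM5 score is an input, never computed here; Bethesda guidelines,
MMRPredict, MMRPro and related models are deliberately not part of the
design; tumor types other than CRC and EC are out of scope; and the tool
does not re-classify variants or replace ACMG assessment — it is a companion
for collecting and weighing tumor-derived evidence, and for sharing it (the
ClinVar synopsis export). See the methods vignette
(`vignettes/mmr-vus-decision-tree.Rmd`) for the full rule set and design
rationale.
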