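Package: lynchtree
Title: Integrated Germline and Tumor Evidence Assessment of Mismatch-Repair
    Variants in Suspected Lynch Syndrome
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A rule-based decision tree for assessing germline variants of
    uncertain significance (VUS) in the DNA mismatch-repair genes MLH1, MSH2,
    MSH6 and PMS2 in patients with suspected Lynch syndrome-related colorectal
    or endometrial cancer. The engine integrates germline findings, clinical
    criteria (PREMM5 threshold, Amsterdam II pedigree evaluation), tumor
    molecular results (BRAF p.V600E, MLH1 promoter methylation, microsatellite
    instability, somatic second hits) and the mismatch-repair
    immunohistochemistry panel into one of four verdicts (POSITIVE, NEUTRAL,
    INCONCLUSIVE, OUT_OF_SCOPE) with evidence codes and an explanatory
    comment. Includes questionnaire schemas for colorectal and endometrial
    cancer, a ClinVar submission-synopsis exporter, a packaged 52-case
    positive-control table with an evaluation harness, exhaustive answer-space
    enumeration for property testing, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    optparse,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
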