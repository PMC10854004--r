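test_that("IHC panels reduce to their canonical pattern", {
  expect_identical(
    canonical_ihc_pattern(ihc_panel("INTACT", "LOST", "LOST", "INTACT")),
    "MSH2_MSH6_LOSS")
  expect_identical(
    canonical_ihc_pattern(ihc_panel("INTACT", "INTACT", "INTACT", "INTACT")),
    "NO_LOSS")
  expect_identical(
    canonical_ihc_pattern(ihc_panel("INTACT", "INTACT", "PARTIAL_LOSS", "LOST")),
    "NOT_ASSESSABLE")
  expect_identical(
    canonical_ihc_pattern(ihc_panel("LOST", "INTACT", "INTACT", "LOST")),
    "MLH1_PMS2_LOSS")
  expect_identical(
    canonical_ihc_pattern(ihc_panel("LOST", "INTACT", "LOST", "LOST")),
    "MSH6_MLH1_PMS2_LOSS")
  expect_identical(
    canonical_ihc_pattern(ihc_panel("LOST", "LOST", "LOST", "LOST")),
    "ALL_FOUR_LOSS")
  expect_identical(
    canonical_ihc_pattern(ihc_panel("LOST", "LOST", "INTACT", "INTACT")),
    "OTHER_COMBINATION")
  # any non-definitive stain anywhere dominates
  for (bad in c("EQUIVOCAL", "PARTIAL_LOSS", "NOT_PERFORMED")) {
    expect_identical(
      canonical_ihc_pattern(ihc_panel(bad, "LOST", "LOST", "LOST")),
      "NOT_ASSESSABLE")
  }
})

test_that("second-hit documentation requires a matching inactivating event", {
  expect_true(biallelic_documented(
    "PMS2", tumor_profile(somatic_events = list(
      somatic_event("PMS2", "one copy loss", "COPY_LOSS")))))
  expect_false(biallelic_documented("MSH6", tumor_profile()))
  expect_false(biallelic_documented(
    "MSH6", tumor_profile(somatic_events = list(
      somatic_event("MSH2", "c.1A>G", inactivating = TRUE)))))
  # a non-inactivating SNV does not count, the override does
  expect_false(biallelic_documented(
    "PMS2", tumor_profile(somatic_events = list(
      somatic_event("PMS2", "c.404T>C (p.L135P)", inactivating = FALSE)))))
  expect_true(biallelic_documented(
    "MSH6", tumor_profile(biallelic_documented_override = TRUE)))
})

test_that("sporadic-etiology check follows the CRC/EC test asymmetry", {
  # CRC: a negative BRAF alone excludes sporadic etiology
  expect_identical(
    sporadic_etiology_excluded("CRC", tumor_profile(braf_v600e = "NEGATIVE")),
    "EXCLUDED")
  # EC: methylation testing is required; BRAF is never consulted
  expect_identical(
    sporadic_etiology_excluded("EC", tumor_profile(braf_v600e = "NEGATIVE")),
    "UNTESTED")
  expect_identical(
    sporadic_etiology_excluded("EC", tumor_profile(
      mlh1_promoter_methylation = "NEGATIVE")), "EXCLUDED")
  # positive methylation dominates everything
  expect_identical(
    sporadic_etiology_excluded("CRC", tumor_profile(
      braf_v600e = "NEGATIVE", mlh1_promoter_methylation = "POSITIVE")),
    "POSITIVE_METHYLATION")
  expect_identical(
    sporadic_etiology_excluded("CRC", tumor_profile(
      braf_v600e = "POSITIVE", mlh1_promoter_methylation = "NEGATIVE")),
    "POSITIVE_BRAF")
  expect_identical(
    sporadic_etiology_excluded("EC", tumor_profile(braf_v600e = "POSITIVE")),
    "UNTESTED")
})

test_that("structural gates report every failing requirement", {
  case <- full_msh2_crc_case()
  expect_identical(structural_gate_codes(case), character())

  # EC case: low PREMM and no second hit -> both codes, nothing else
  case <- full_msh2_crc_case(
    cancer_type = "EC",
    queried_variant = germline_finding("PMS2", "c.2117delA"),
    clinical = clinical_evidence(premm5_percent = 2.0),
    tumor = tumor_profile(mlh1_promoter_methylation = "POSITIVE",
                          msi = "MSI_HIGH"),
    ihc = ihc_panel("LOST", "INTACT", "INTACT", "LOST"))
  expect_setequal(structural_gate_codes(case), c("EC I-II", "EC I-IV"))

  # normal IHC alone
  case <- full_msh2_crc_case(ihc = ihc_panel("INTACT", "INTACT", "INTACT",
                                             "INTACT"))
  expect_identical(structural_gate_codes(case), "CRC I-VII")

  # everything missing at once
  case <- evidence_case("CRC", germline_finding("MLH1", "c.1A>G"))
  expect_gte(length(structural_gate_codes(case)), 3L)
})

test_that("MLH1 stage routes the sporadic check to NEUTRAL, not a gate", {
  pos <- assess_case(full_mlh1_crc_case())
  expect_identical(pos$category, "POSITIVE")
  expect_match(pos$codes, "^CRC II-")

  # methylation positive -> NEUTRAL (uncertainty, not refusal)
  case <- full_mlh1_crc_case(tumor = tumor_profile(
    braf_v600e = "NEGATIVE", mlh1_promoter_methylation = "POSITIVE",
    msi = "MSI_HIGH",
    somatic_events = list(somatic_event("MLH1", "del", inactivating = TRUE))))
  expect_identical(assess_case(case)$category, "NEUTRAL")

  # both sporadic tests unavailable -> NEUTRAL
  case <- full_mlh1_crc_case(tumor = tumor_profile(
    msi = "MSI_HIGH",
    somatic_events = list(somatic_event("MLH1", "del", inactivating = TRUE))))
  expect_identical(assess_case(case)$category, "NEUTRAL")

  # isolated MLH1 loss is unusual -> NEUTRAL
  case <- full_mlh1_crc_case(ihc = ihc_panel("LOST", "INTACT", "INTACT",
                                             "INTACT"))
  expect_identical(assess_case(case)$category, "NEUTRAL")

  # secondary MSH6 loss stays POSITIVE
  case <- full_mlh1_crc_case(ihc = ihc_panel("LOST", "INTACT", "LOST",
                                             "LOST"))
  expect_identical(assess_case(case)$category, "POSITIVE")
})

test_that("PMS2 stage treats MLH1+PMS2 loss as NEUTRAL regardless of sporadic tests", {
  base <- list(
    cancer_type = "CRC",
    queried_variant = germline_finding("PMS2", "c.137G>T", "p.S46I"),
    clinical = clinical_evidence(premm5_percent = 4.7),
    ihc = ihc_panel("LOST", "INTACT", "INTACT", "LOST"))
  for (meth in c("NEGATIVE", "POSITIVE", "NOT_TESTED")) {
    case <- do.call(full_msh2_crc_case, utils::modifyList(base, list(
      tumor = tumor_profile(
        braf_v600e = "NEGATIVE", mlh1_promoter_methylation = meth,
        msi = "MSI_HIGH",
        somatic_events = list(somatic_event("PMS2", "del",
                                            inactivating = TRUE))))))
    expect_identical(assess_case(case)$category, "NEUTRAL")
  }
  # isolated PMS2 loss: POSITIVE only when sporadic etiology is excluded
  case <- do.call(full_msh2_crc_case, utils::modifyList(base, list(
    ihc = ihc_panel("INTACT", "INTACT", "INTACT", "LOST"),
    tumor = tumor_profile(
      braf_v600e = "NEGATIVE", msi = "MSI_HIGH",
      somatic_events = list(somatic_event("PMS2", "del",
                                          inactivating = TRUE))))))
  expect_identical(assess_case(case)$category, "POSITIVE")
  expect_match(assess_case(case)$codes, "^CRC III-")

  case$tumor$mlh1_promoter_methylation <- "POSITIVE"
  v <- assess_case(case)
  expect_identical(v$category, "INCONCLUSIVE")
  expect_identical(v$codes, "CRC I-IV")
})

test_that("MSH2/MSH6 stages refuse when sporadic etiology is not excluded", {
  case <- full_msh2_crc_case(tumor = tumor_profile(
    msi = "MSI_HIGH",
    somatic_events = list(somatic_event("MSH2", "c.2334C>A",
                                        inactivating = TRUE))))
  v <- assess_case(case)
  expect_identical(v$category, "INCONCLUSIVE")
  expect_setequal(v$codes, c("CRC I-III", "CRC I-IV"))

  # MSH6 VUS, isolated MSH6 loss, sporadic excluded -> POSITIVE V family
  case <- full_msh2_crc_case(
    queried_variant = germline_finding("MSH6", "c.3436C>T"),
    tumor = tumor_profile(
      braf_v600e = "NEGATIVE", msi = "MSI_HIGH",
      somatic_events = list(somatic_event("MSH6", "del",
                                          inactivating = TRUE))),
    ihc = ihc_panel("INTACT", "INTACT", "LOST", "INTACT"))
  v <- assess_case(case)
  expect_identical(v$category, "POSITIVE")
  expect_match(v$codes, "^CRC V-I$")

  # MSH2+MSH6 loss with an MSH6 VUS suggests MSH2 -> NEUTRAL
  case$ihc <- ihc_panel("INTACT", "LOST", "LOST", "INTACT")
  expect_identical(assess_case(case)$category, "NEUTRAL")

  # all-four loss with MSH2 VUS -> NEUTRAL
  case <- full_msh2_crc_case(ihc = ihc_panel("LOST", "LOST", "LOST", "LOST"))
  expect_identical(assess_case(case)$category, "NEUTRAL")
})

test_that("combinations outside the enumerated branches are OUT_OF_SCOPE", {
  # MSH6 VUS in EC with isolated PMS2 loss: no branch covers this
  case <- full_msh2_crc_case(
    cancer_type = "EC",
    queried_variant = germline_finding("MSH6", "c.10C>T"),
    clinical = clinical_evidence(premm5_percent = 4),
    tumor = tumor_profile(
      mlh1_promoter_methylation = "NEGATIVE", msi = "MSI_HIGH",
      somatic_events = list(somatic_event("MSH6", "del",
                                          inactivating = TRUE))),
    ihc = ihc_panel("INTACT", "INTACT", "INTACT", "LOST"))
  v <- assess_case(case)
  expect_identical(v$category, "OUT_OF_SCOPE")
  expect_length(v$codes, 0L)
  expect_match(v$comment, "falls outside of the current parameters")
})

test_that("verdict comments name the gene, category and code meanings", {
  v <- assess_case(full_msh2_crc_case())
  expect_identical(v$category, "POSITIVE")
  expect_match(v$comment, "MSH2")

  case <- full_mlh1_crc_case(ihc = ihc_panel("INTACT", "INTACT", "INTACT",
                                             "INTACT"))
  v <- assess_case(case)
  expect_identical(v$codes, "CRC I-VII")
  expect_match(v$comment, "IHC")
  expect_match(v$comment, "absent")
})

test_that("assessment is deterministic and the synopsis mirrors the schema", {
  case <- full_msh2_crc_case()
  v1 <- assess_case(case)
  v2 <- assess_case(case)
  expect_equal(v1, v2)
  expect_length(v1$synopsis$question, 11L)
  expect_identical(v1$synopsis$question,
                   vapply(schema_for("CRC"), function(q) q$prompt,
                          character(1)))
})

test_that("paper-style composite cases assess as printed", {
  # subject 31-style record: complete evidence, MSH2, family IV
  v <- assess_case(full_msh2_crc_case(
    clinical = clinical_evidence(premm5_percent = 6.7),
    tumor = tumor_profile(
      braf_v600e = "NOT_TESTED", mlh1_promoter_methylation = "NEGATIVE",
      msi = "MSI_HIGH",
      somatic_events = list(somatic_event("MSH2", "c.2334C>A (p.C778*)",
                                          inactivating = TRUE)))))
  expect_identical(v$category, "POSITIVE")
  expect_match(v$codes, "^CRC IV-")

  # subject 20-style record: no somatic second hit -> biallelic gate
  v <- assess_case(full_mlh1_crc_case(
    clinical = clinical_evidence(premm5_percent = 20.3),
    tumor = tumor_profile(braf_v600e = "NEGATIVE", msi = "MSI_HIGH")))
  expect_identical(v$category, "INCONCLUSIVE")
  expect_identical(v$codes, "CRC I-V")

  # nothing tested at all -> at least three gates
  v <- assess_case(evidence_case("CRC", germline_finding("MLH1", "c.1A>G")))
  expect_identical(v$category, "INCONCLUSIVE")
  expect_gte(length(v$codes), 3L)
})

test_that("invalid cases are refused with their violations listed", {
  case <- full_msh2_crc_case(
    queried_variant = germline_finding("MSH2", ""))
  expect_error(assess_case(case), "cdna")
})

test_that("the code registry is unique and covers every emitted code", {
  reg <- evidence_codes()
  expect_false(anyDuplicated(reg$code) > 0)
  expect_true(all(reg$family %in% c("I", "II", "III", "IV", "V")))
  # every code reachable on the fixture cohort is registered
  recs <- load_control_table()
  emitted <- unique(unlist(lapply(recs, function(r)
    assess_case(control_to_case(r))$codes)))
  expect_true(all(emitted %in% reg$code))
})
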