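test_that("PREMM5 threshold is inclusive at 2.5% and absent scores fail", {
  expect_true(premm5_meets_threshold(2.5))
  expect_false(premm5_meets_threshold(2.4))
  expect_false(premm5_meets_threshold(NA))
  expect_false(premm5_meets_threshold(NULL))
  expect_true(premm5_meets_threshold(2.4, threshold = 2))  # configurable
  expect_error(premm5_meets_threshold(5, threshold = 0))
})

test_that("clinical criteria are a PREMM5/Amsterdam disjunction", {
  expect_true(clinical_criteria_met(clinical_evidence(6.7, "UNKNOWN")))
  expect_true(clinical_criteria_met(clinical_evidence(NA_real_, "TRUE")))
  expect_false(clinical_criteria_met(clinical_evidence(1.3, "FALSE")))
  expect_false(clinical_criteria_met(clinical_evidence(NA_real_, "UNKNOWN")))
  # monotone non-decreasing in the score
  scores <- seq(0, 10, by = 0.5)
  met <- vapply(scores, function(s)
    clinical_criteria_met(clinical_evidence(s, "FALSE")), logical(1))
  expect_true(all(diff(met) >= 0))
})

test_that("relationship degrees follow genetic convention", {
  ped <- amsterdam_positive_pedigree()
  expect_identical(relationship_degree(ped, "mother", "proband"), 1L)
  expect_identical(relationship_degree(ped, "mother", "uncle"), 1L)   # full sibs
  expect_identical(relationship_degree(ped, "gm", "proband"), 2L)     # grandparent
  expect_identical(relationship_degree(ped, "uncle", "proband"), 2L)  # uncle
  expect_identical(relationship_degree(ped, "proband", "proband"), 0L)
  expect_error(relationship_degree(ped, "nobody", "gm"), "nobody")
  # members with no parent-link path at all are unrelated
  ped2 <- pedigree("a", list(relative("a"), relative("b")))
  expect_identical(relationship_degree(ped2, "a", "b"), Inf)
})

test_that("half-siblings are second degree", {
  ped <- pedigree("a", list(
    relative("m", generation = -1L),
    relative("f1", generation = -1L),
    relative("f2", generation = -1L),
    relative("a", mother_id = "m", father_id = "f1", generation = 0L),
    relative("b", mother_id = "m", father_id = "f2", generation = 0L)))
  expect_identical(relationship_degree(ped, "a", "b"), 2L)
})

test_that("relationship degree is symmetric", {
  ped <- amsterdam_positive_pedigree()
  ids <- c("gm", "gf", "mother", "uncle", "father", "proband")
  for (a in ids) for (b in ids) {
    expect_identical(relationship_degree(ped, a, b),
                     relationship_degree(ped, b, a))
  }
})

test_that("pedigrees reject unknown parents and cyclic links", {
  expect_error(pedigree("a", list(relative("a", mother_id = "ghost"))),
               "ghost")
  expect_error(pedigree("a", list(
    relative("a", mother_id = "b", generation = 0L),
    relative("b", mother_id = "a", generation = -1L))), "cyclic")
  expect_error(pedigree("x", list(relative("a"))), "proband")
})

test_that("a qualifying three-relative family meets Amsterdam II", {
  res <- amsterdam_ii_met(parent_two_children_pedigree())
  expect_true(res$met)
  expect_length(res$reasons, 0L)
})

test_that("each Amsterdam II clause is individually required", {
  # fewer than three affected
  ped <- pedigree("c1", list(
    relative("p", generation = -1L,
             diagnoses = data.frame(cancer = "colorectal", age = 45)),
    relative("c1", mother_id = "p", generation = 0L,
             diagnoses = data.frame(cancer = "endometrial", age = 52))),
    fap_excluded = TRUE)
  res <- amsterdam_ii_met(ped)
  expect_false(res$met)
  expect_match(res$reasons, "fewer than three", all = FALSE)

  # all diagnoses at >= 50 (boundary: exactly 50 does not qualify)
  res <- amsterdam_ii_met(parent_two_children_pedigree(parent_age = 50))
  expect_false(res$met)
  expect_match(res$reasons, "age 50", all = FALSE)
  # one year earlier qualifies
  expect_true(amsterdam_ii_met(parent_two_children_pedigree(parent_age = 49))$met)

  # colorectal cancer present but FAP not excluded
  res <- amsterdam_ii_met(parent_two_children_pedigree(fap_excluded = FALSE))
  expect_false(res$met)
  expect_match(res$reasons, "polyposis", all = FALSE)

  # single generation only
  ped <- pedigree("a", list(
    relative("m", generation = -1L),
    relative("f", generation = -1L),
    relative("a", mother_id = "m", father_id = "f", generation = 0L,
             diagnoses = data.frame(cancer = "colorectal", age = 45)),
    relative("b", mother_id = "m", father_id = "f", generation = 0L,
             diagnoses = data.frame(cancer = "colorectal", age = 47)),
    relative("c", mother_id = "m", father_id = "f", generation = 0L,
             diagnoses = data.frame(cancer = "endometrial", age = 48))),
    fap_excluded = TRUE)
  res <- amsterdam_ii_met(ped)
  expect_false(res$met)
  expect_match(res$reasons, "successive generations", all = FALSE)

  # three affected but no first-degree hub: grandparent, parent-in-law gap
  ped <- pedigree("a", list(
    relative("gm", generation = -2L,
             diagnoses = data.frame(cancer = "colorectal", age = 45)),
    relative("m", mother_id = "gm", generation = -1L),
    relative("a", mother_id = "m", generation = 0L,
             diagnoses = data.frame(cancer = "colorectal", age = 48)),
    relative("cousin_spouse", generation = 0L,
             diagnoses = data.frame(cancer = "endometrial", age = 44))),
    fap_excluded = TRUE)
  res <- amsterdam_ii_met(ped)
  expect_false(res$met)
  expect_match(res$reasons, "first-degree", all = FALSE)
})

test_that("non-Lynch tumors do not count toward Amsterdam II", {
  ped <- parent_two_children_pedigree()
  res <- amsterdam_ii_met(ped, ls_cancer_labels = c("pancreatic"))
  expect_false(res$met)
})

test_that("adding an affected first-degree relative never breaks Amsterdam II", {
  base <- parent_two_children_pedigree()
  expect_true(amsterdam_ii_met(base)$met)
  grown <- pedigree(
    proband_id = "c1",
    members = c(base$members, list(
      relative("c3", mother_id = "p", father_id = "s", generation = 0L,
               diagnoses = data.frame(cancer = "ureter", age = 61)))),
    fap_excluded = TRUE)
  expect_true(amsterdam_ii_met(grown)$met)
})

test_that("pedigrees load from the tab-delimited format", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "# proband: c1",
    "# fap_excluded: TRUE",
    "id\tmother_id\tfather_id\tgeneration\tdiagnoses",
    "p\t\t\t-1\tcolorectal@45",
    "s\t\t\t-1\t",
    "c1\tp\ts\t0\tendometrial@52",
    "c2\tp\ts\t0\tcolorectal@55;ureter@60"),
    path)
  ped <- read_pedigree(path)
  expect_identical(ped$proband_id, "c1")
  expect_true(ped$fap_excluded)
  expect_length(ped$members, 4L)
  expect_true(amsterdam_ii_met(ped)$met)
})
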