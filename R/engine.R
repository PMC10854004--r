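# The decision tree: structural eligibility gates, sporadic-etiology
# exclusion, IHC pattern canonicalization, per-gene verdict logic and the
# top-level case assessment.
#
# Evidence codes are strings "CRC I-II", "EC IV-I", ...: family I codes flag
# absent/adverse key evidence (INCONCLUSIVE); families II-V carry the
# per-gene POSITIVE/NEUTRAL scenarios (II = MLH1, III = PMS2, IV = MSH2,
# V = MSH6). Sub-indices inside families II-V follow this package's own
# deterministic enumeration over (sporadic-marker configuration x IHC
# pattern); only the family conveys gene/meaning.

IHC_PATTERNS <- c("NO_LOSS", "MLH1_PMS2_LOSS", "ISOLATED_MLH1",
                  "ISOLATED_PMS2", "MSH2_MSH6_LOSS", "ISOLATED_MSH2",
                  "ISOLATED_MSH6", "MSH6_MLH1_PMS2_LOSS", "ALL_FOUR_LOSS",
                  "OTHER_COMBINATION", "NOT_ASSESSABLE")

# lost-protein mask (MLH1, MSH2, MSH6, PMS2) -> canonical pattern
.pattern_by_mask <- local({
  m <- rep("OTHER_COMBINATION", 16L)
  names(m) <- vapply(0:15, function(i) {
    paste(as.integer(intToBits(i)[1:4]), collapse = "")
  }, character(1))
  m[["0000"]] <- "NO_LOSS"
  m[["1001"]] <- "MLH1_PMS2_LOSS"       # MLH1 + PMS2
  m[["1000"]] <- "ISOLATED_MLH1"
  m[["0001"]] <- "ISOLATED_PMS2"
  m[["0110"]] <- "MSH2_MSH6_LOSS"       # MSH2 + MSH6
  m[["0100"]] <- "ISOLATED_MSH2"
  m[["0010"]] <- "ISOLATED_MSH6"
  m[["1011"]] <- "MSH6_MLH1_PMS2_LOSS"  # MLH1 + MSH6 + PMS2
  m[["1111"]] <- "ALL_FOUR_LOSS"
  m
})

#' Canonical IHC staining pattern
#'
#' Reduces a four-protein panel to one named pattern label. Any equivocal,
#' partial or unperformed stain makes the panel `NOT_ASSESSABLE` (such
#' patterns are not incorporated in the assessment); otherwise the set of
#' lost proteins maps to its named label or `OTHER_COMBINATION`.
#'
#' @param panel An [ihc_panel()].
#' @return One of the canonical pattern labels.
#' @examples
#' canonical_ihc_pattern(ihc_panel("INTACT", "LOST", "LOST", "INTACT"))
#' @export
canonical_ihc_pattern <- function(panel) {
  s <- c(panel$mlh1, panel$msh2, panel$msh6, panel$pms2)
  if (any(s == "EQUIVOCAL" | s == "PARTIAL_LOSS" | s == "NOT_PERFORMED")) {
    return("NOT_ASSESSABLE")
  }
  .pattern_by_mask[[paste(as.integer(s == "LOST"), collapse = "")]]
}

#' Is a somatic second hit documented for the queried gene?
#'
#' True when the questionnaire-level override asserts it, or when some
#' somatic event in the queried gene is inactivating (copy losses count as
#' inactivating regardless of the annotator flag). The somatic and germline
#' alterations are presumed in trans whenever a qualifying event exists;
#' phase is not modeled.
#'
#' @param queried_gene One of `MMR_GENES`.
#' @param tumor A [tumor_profile()].
#' @return Logical.
#' @export
biallelic_documented <- function(queried_gene, tumor) {
  if (isTRUE(tumor$biallelic_documented_override)) return(TRUE)
  for (ev in tumor$somatic_events) {
    if (ev$gene == queried_gene &&
        (ev$kind == "COPY_LOSS" || isTRUE(ev$inactivating))) {
      return(TRUE)
    }
  }
  FALSE
}

#' Sporadic-etiology check (BRAF / MLH1 promoter methylation)
#'
#' MLH1 promoter methylation definitionally marks sporadic MMR-deficient
#' tumors; BRAF p.V600E marks roughly half of sporadic MMR-deficient
#' colorectal cancers and is never consulted for endometrial cancer. For
#' CRC, a negative result on either test suffices to exclude sporadic
#' etiology (a negative BRAF result in the absence of methylation testing
#' is acceptable); for EC only a negative methylation result does.
#'
#' @param cancer_type `"CRC"` or `"EC"`.
#' @param tumor A [tumor_profile()].
#' @return `"EXCLUDED"`, `"POSITIVE_METHYLATION"`, `"POSITIVE_BRAF"` or
#'   `"UNTESTED"`.
#' @export
sporadic_etiology_excluded <- function(cancer_type, tumor) {
  meth <- tumor$mlh1_promoter_methylation
  if (meth == "POSITIVE") return("POSITIVE_METHYLATION")
  if (cancer_type == "CRC" && tumor$braf_v600e == "POSITIVE") {
    return("POSITIVE_BRAF")
  }
  if (meth == "NEGATIVE") return("EXCLUDED")
  if (cancer_type == "CRC" && tumor$braf_v600e == "NEGATIVE") return("EXCLUDED")
  "UNTESTED"
}

# gate/sporadic code ids per cancer type
.gate_code <- function(cancer_type, gate) {
  crc <- c(single_vus = "I-I", clinical = "I-II", braf = "I-III",
           methylation = "I-IV", biallelic = "I-V", msi = "I-VI",
           ihc = "I-VII")
  ec <- c(single_vus = "I-I", clinical = "I-II", methylation = "I-III",
          biallelic = "I-IV", msi = "I-V", ihc = "I-VI")
  id <- if (cancer_type == "CRC") crc[[gate]] else ec[[gate]]
  paste(cancer_type, id)
}

#' Structural eligibility gates
#'
#' Evaluates every structural requirement of the decision tree and returns
#' the codes of ALL failing gates: the single-VUS gate (exactly one germline
#' MMR VUS, no other pathogenic germline MMR alteration, no EPCAM 3'
#' deletion), the clinical gate (PREMM5 or Amsterdam II), the biallelic gate
#' (documented somatic second hit), the MSI gate (MSI-high required) and the
#' IHC gate (loss of at least one protein on an assessable panel). The
#' BRAF/methylation sporadic check is not a structural gate; it is routed
#' per gene in [gene_stage_assess()].
#'
#' @param case A valid [evidence_case()].
#' @param threshold PREMM5 threshold in percent.
#' @return Character vector of failing gate codes (empty if all pass).
#' @export
structural_gate_codes <- function(case, threshold = 2.5) {
  ct <- case$cancer_type
  codes <- character()
  if (case$germline_vus_count != 1L || case$other_pathogenic_mmr_germline ||
      case$epcam_3prime_deletion) {
    codes <- c(codes, .gate_code(ct, "single_vus"))
  }
  if (!clinical_criteria_met(case$clinical, threshold)) {
    codes <- c(codes, .gate_code(ct, "clinical"))
  }
  if (!biallelic_documented(case$queried_variant$gene, case$tumor)) {
    codes <- c(codes, .gate_code(ct, "biallelic"))
  }
  if (case$tumor$msi != "MSI_HIGH") {
    codes <- c(codes, .gate_code(ct, "msi"))
  }
  pat <- canonical_ihc_pattern(case$ihc)
  if (pat == "NO_LOSS" || pat == "NOT_ASSESSABLE") {
    codes <- c(codes, .gate_code(ct, "ihc"))
  }
  codes
}

# codes flagged when the sporadic check blocks a gene-stage assessment
.sporadic_gate_codes <- function(cancer_type, sporadic) {
  if (sporadic == "POSITIVE_METHYLATION") {
    .gate_code(cancer_type, "methylation")
  } else if (sporadic == "POSITIVE_BRAF") {
    .gate_code(cancer_type, "braf")
  } else {  # UNTESTED
    if (cancer_type == "CRC") {
      c(.gate_code(cancer_type, "braf"), .gate_code(cancer_type, "methylation"))
    } else {
      .gate_code(cancer_type, "methylation")
    }
  }
}

.fragment <- function(category, code, note) {
  list(category = category, codes = code, note = note)
}

#' Per-gene verdict logic
#'
#' Applies after every structural gate passes. Routes the sporadic
#' BRAF/methylation check per gene and maps the canonical IHC pattern to a
#' POSITIVE, NEUTRAL, INCONCLUSIVE or OUT_OF_SCOPE fragment:
#'
#' * **MLH1**: a positive or untested sporadic check is NEUTRAL; with
#'   sporadic etiology excluded, loss of MLH1+PMS2 (with or without
#'   secondary MSH6 loss) or isolated PMS2 loss is POSITIVE; isolated MLH1
#'   loss is unusual, hence NEUTRAL; other patterns are out of scope.
#' * **PMS2**: MLH1+PMS2 loss is NEUTRAL regardless of the sporadic check
#'   (it suggests an MLH1 alteration); isolated PMS2 loss is POSITIVE when
#'   sporadic etiology is excluded, otherwise INCONCLUSIVE with the
#'   corresponding sporadic gate code; other patterns are out of scope.
#' * **MSH2**: a non-excluded sporadic check is INCONCLUSIVE with the gate
#'   code; otherwise MSH2+MSH6 loss or isolated MSH6 loss is POSITIVE;
#'   isolated MSH2 loss and all-four loss are NEUTRAL; other patterns out
#'   of scope.
#' * **MSH6**: a non-excluded sporadic check is INCONCLUSIVE with the gate
#'   code; otherwise isolated MSH6 loss is POSITIVE; MSH2+MSH6 loss
#'   (suggesting MSH2) and MLH1+PMS2+MSH6 loss (secondary MSH6 loss) are
#'   NEUTRAL; other patterns out of scope.
#'
#' @param case A valid [evidence_case()] with all structural gates passing.
#' @param threshold PREMM5 threshold in percent.
#' @param check_gates Verify the precondition that no structural gate fails
#'   (the top-level [assess_case()] has already established it).
#' @return List with `category`, `codes` and `note` (scenario text).
#' @export
gene_stage_assess <- function(case, threshold = 2.5, check_gates = TRUE) {
  if (check_gates) {
    gates <- structural_gate_codes(case, threshold)
    if (length(gates)) {
      stop("gene_stage_assess requires all structural gates to pass; failing: ",
           paste(gates, collapse = ", "), call. = FALSE)
    }
  }
  ct <- case$cancer_type
  gene <- case$queried_variant$gene
  pat <- canonical_ihc_pattern(case$ihc)
  sp <- sporadic_etiology_excluded(ct, case$tumor)
  meth_neg <- case$tumor$mlh1_promoter_methylation == "NEGATIVE"
  oos <- .fragment("OUT_OF_SCOPE", character(),
                   "the combination of evidence falls outside of the current parameters of the algorithm")

  if (gene == "MLH1") {
    fam <- function(id) paste(ct, id)
    if (sp == "POSITIVE_METHYLATION") {
      return(.fragment("NEUTRAL", fam("II-V"),
                       "the significance of the VUS remains uncertain because MLH1 promoter methylation testing is positive"))
    }
    if (sp == "POSITIVE_BRAF") {
      return(.fragment("NEUTRAL", fam("II-VI"),
                       "the significance of the VUS remains uncertain because BRAF p.V600E testing is positive"))
    }
    if (sp == "UNTESTED") {
      return(.fragment("NEUTRAL", fam("II-VII"),
                       "the significance of the VUS remains uncertain because sporadic-etiology test results are unavailable"))
    }
    if (pat == "MLH1_PMS2_LOSS") {
      return(.fragment("POSITIVE", fam(if (meth_neg) "II-I" else "II-II"),
                       "loss of MLH1 and PMS2 in tumor nuclei is compatible with biallelic MLH1 inactivation"))
    }
    if (pat == "MSH6_MLH1_PMS2_LOSS") {
      return(.fragment("POSITIVE", fam("II-IV"),
                       "loss of MLH1 and PMS2 with secondary loss of MSH6 is compatible with biallelic MLH1 inactivation"))
    }
    if (pat == "ISOLATED_PMS2") {
      return(.fragment("POSITIVE", fam("II-III"),
                       "isolated loss of PMS2 is also compatible with MLH1 alterations that retain nonfunctional MLH1 expression"))
    }
    if (pat == "ISOLATED_MLH1") {
      return(.fragment("NEUTRAL", fam("II-VIII"),
                       "isolated loss of MLH1 is unusual; a review of the IHC findings and potentially repeat IHC is warranted"))
    }
    return(oos)
  }

  if (gene == "PMS2") {
    if (pat == "MLH1_PMS2_LOSS") {
      idx <- if (ct == "CRC") {
        switch(sp, EXCLUDED = "III-IV", POSITIVE_METHYLATION = "III-V",
               POSITIVE_BRAF = "III-VI", UNTESTED = "III-VII")
      } else {
        if (sp == "EXCLUDED") "III-II" else "III-III"
      }
      return(.fragment("NEUTRAL", paste(ct, idx),
                       "loss of both MLH1 and PMS2 suggests that the MLH1 gene is altered, regardless of MLH1 promoter methylation and/or BRAF results"))
    }
    if (pat == "ISOLATED_PMS2") {
      if (sp == "EXCLUDED") {
        idx <- if (ct == "CRC") { if (meth_neg) "III-I" else "III-III" } else "III-I"
        return(.fragment("POSITIVE", paste(ct, idx),
                         "isolated loss of PMS2 in tumor nuclei supports biallelic inactivation of the PMS2 gene"))
      }
      return(.fragment("INCONCLUSIVE", .sporadic_gate_codes(ct, sp),
                       "sporadic etiology is not excluded"))
    }
    return(oos)
  }

  # MSH2 / MSH6: the sporadic check blocks the assessment outright
  if (sp != "EXCLUDED") {
    return(.fragment("INCONCLUSIVE", .sporadic_gate_codes(ct, sp),
                     "sporadic etiology is not excluded"))
  }
  if (gene == "MSH2") {
    fam <- function(id) paste(ct, id)
    if (pat == "MSH2_MSH6_LOSS") {
      return(.fragment("POSITIVE", fam("IV-I"),
                       "loss of MSH2 and MSH6 in tumor nuclei is compatible with biallelic MSH2 inactivation and degradation of its dimerization partner"))
    }
    if (pat == "ISOLATED_MSH6") {
      return(.fragment("POSITIVE", fam("IV-II"),
                       "isolated loss of MSH6 is also compatible, as certain MSH2 alterations retain MSH2 expression with loss of MSH6"))
    }
    if (pat == "ISOLATED_MSH2") {
      return(.fragment("NEUTRAL", fam("IV-III"),
                       "an isolated loss of MSH2 is an unusual IHC pattern; a review of the IHC findings is recommended"))
    }
    if (pat == "ALL_FOUR_LOSS") {
      return(.fragment("NEUTRAL", fam("IV-III"),
                       "loss of all four MMR proteins warrants detailed review, as loss of MLH1 and PMS2 could be subclonal"))
    }
    return(oos)
  }
  if (gene == "MSH6") {
    fam <- function(id) paste(ct, id)
    if (pat == "ISOLATED_MSH6") {
      return(.fragment("POSITIVE", fam("V-I"),
                       "loss of only MSH6 in tumor nuclei supports biallelic inactivation of the MSH6 gene"))
    }
    if (pat == "MSH2_MSH6_LOSS") {
      return(.fragment("NEUTRAL", fam("V-II"),
                       "loss of both MSH2 and MSH6 suggests a likely alteration in MSH2"))
    }
    if (pat == "MSH6_MLH1_PMS2_LOSS") {
      return(.fragment("NEUTRAL", fam("V-III"),
                       "loss of MSH6 together with MLH1 and PMS2 suggests a secondary loss of MSH6"))
    }
    return(oos)
  }
  oos
}

#' Evidence-code registry
#'
#' All codes the engine can emit, with cancer type, family and meaning.
#'
#' @return Data frame with columns `code`, `cancer_type`, `family`, `meaning`.
#' @export
evidence_codes <- function() {
  rows <- list()
  add <- function(ct, id, meaning) {
    rows[[length(rows) + 1L]] <<- data.frame(
      code = paste(ct, id), cancer_type = ct,
      family = sub("-.*$", "", id), meaning = meaning)
  }
  gate_meanings <- c(
    single_vus = "more than one germline MMR VUS, an additional pathogenic germline MMR alteration, or an EPCAM 3' deletion is present",
    clinical = "clinical criteria (PREMM5 >= threshold or Amsterdam II) are not met",
    braf = "somatic BRAF p.V600E testing is positive or unavailable",
    methylation = "MLH1 promoter methylation testing is positive or unavailable",
    biallelic = "somatic inactivation of the second allele is not documented",
    msi = "microsatellite instability (MSI-high) is not documented",
    ihc = "IHC shows no loss of MMR protein expression, or the panel is not assessable")
  for (g in c("single_vus", "clinical", "braf", "methylation", "biallelic",
              "msi", "ihc")) {
    if (g == "braf") { add("CRC", "I-III", gate_meanings[[g]]); next }
    add("CRC", sub("^CRC ", "", .gate_code("CRC", g)), gate_meanings[[g]])
  }
  for (g in c("single_vus", "clinical", "methylation", "biallelic", "msi",
              "ihc")) {
    add("EC", sub("^EC ", "", .gate_code("EC", g)), gate_meanings[[g]])
  }
  fam_codes <- list(
    c("II-I", "POSITIVE: MLH1 VUS with loss of MLH1 and PMS2, methylation tested negative"),
    c("II-II", "POSITIVE: MLH1 VUS with loss of MLH1 and PMS2, sporadic etiology excluded by BRAF"),
    c("II-III", "POSITIVE: MLH1 VUS with isolated loss of PMS2"),
    c("II-IV", "POSITIVE: MLH1 VUS with loss of MLH1, PMS2 and secondary MSH6 loss"),
    c("II-V", "NEUTRAL: MLH1 VUS with positive MLH1 promoter methylation"),
    c("II-VI", "NEUTRAL: MLH1 VUS with positive BRAF p.V600E"),
    c("II-VII", "NEUTRAL: MLH1 VUS with sporadic-etiology tests unavailable"),
    c("II-VIII", "NEUTRAL: MLH1 VUS with unusual isolated loss of MLH1"),
    c("III-I", "POSITIVE: PMS2 VUS with isolated loss of PMS2, methylation tested negative"),
    c("III-III", "POSITIVE: PMS2 VUS with isolated loss of PMS2, sporadic etiology excluded by BRAF"),
    c("III-IV", "NEUTRAL: PMS2 VUS with loss of MLH1 and PMS2 (suggests MLH1), sporadic etiology excluded"),
    c("III-V", "NEUTRAL: PMS2 VUS with loss of MLH1 and PMS2, methylation positive"),
    c("III-VI", "NEUTRAL: PMS2 VUS with loss of MLH1 and PMS2, BRAF positive"),
    c("III-VII", "NEUTRAL: PMS2 VUS with loss of MLH1 and PMS2, sporadic tests unavailable"),
    c("IV-I", "POSITIVE: MSH2 VUS with loss of MSH2 and MSH6"),
    c("IV-II", "POSITIVE: MSH2 VUS with isolated loss of MSH6"),
    c("IV-III", "NEUTRAL: MSH2 VUS with unusual IHC (isolated MSH2 loss or all four proteins lost)"),
    c("V-I", "POSITIVE: MSH6 VUS with isolated loss of MSH6"),
    c("V-II", "NEUTRAL: MSH6 VUS with loss of MSH2 and MSH6 (suggests MSH2)"),
    c("V-III", "NEUTRAL: MSH6 VUS with loss of MSH6, MLH1 and PMS2 (secondary MSH6 loss)"))
  for (fc in fam_codes) add("CRC", fc[1], fc[2])
  ec_fam <- list(
    c("II-I", "POSITIVE: MLH1 VUS with loss of MLH1 and PMS2"),
    c("II-II", "POSITIVE: MLH1 VUS with compatible alternate IHC pattern"),
    c("II-III", "POSITIVE: MLH1 VUS with isolated loss of PMS2"),
    c("II-IV", "POSITIVE: MLH1 VUS with loss of MLH1, PMS2 and secondary MSH6 loss"),
    c("II-V", "NEUTRAL: MLH1 VUS with positive MLH1 promoter methylation"),
    c("II-VII", "NEUTRAL: MLH1 VUS with methylation testing unavailable"),
    c("II-VIII", "NEUTRAL: MLH1 VUS with unusual isolated loss of MLH1"),
    c("III-I", "POSITIVE: PMS2 VUS with isolated loss of PMS2"),
    c("III-II", "NEUTRAL: PMS2 VUS with loss of MLH1 and PMS2, sporadic etiology excluded"),
    c("III-III", "NEUTRAL: PMS2 VUS with loss of MLH1 and PMS2, methylation positive or unavailable"),
    c("IV-I", "POSITIVE: MSH2 VUS with loss of MSH2 and MSH6"),
    c("IV-II", "POSITIVE: MSH2 VUS with isolated loss of MSH6"),
    c("IV-III", "NEUTRAL: MSH2 VUS with unusual IHC (isolated MSH2 loss or all four proteins lost)"),
    c("V-I", "POSITIVE: MSH6 VUS with isolated loss of MSH6"),
    c("V-II", "NEUTRAL: MSH6 VUS with loss of MSH2 and MSH6 (suggests MSH2)"),
    c("V-III", "NEUTRAL: MSH6 VUS with loss of MSH6, MLH1 and PMS2 (secondary MSH6 loss)"))
  for (fc in ec_fam) add("EC", fc[1], fc[2])
  do.call(rbind, rows)
}

.registry_cache <- new.env(parent = emptyenv())

.code_meaning <- function(code) {
  if (is.null(.registry_cache$reg)) .registry_cache$reg <- evidence_codes()
  reg <- .registry_cache$reg
  i <- match(code, reg$code)
  ifelse(is.na(i), "unregistered code", reg$meaning[i])
}

#' Explanatory comment for a verdict
#'
#' Non-empty text naming the queried gene, the category and each code's
#' meaning.
#'
#' @param category Verdict category.
#' @param codes Character vector of evidence codes (may be empty).
#' @param case The assessed [evidence_case()].
#' @param note Optional scenario text from [gene_stage_assess()].
#' @return Character scalar.
#' @export
verdict_comment <- function(category, codes, case, note = NULL) {
  gene <- case$queried_variant$gene
  var <- paste0(gene, " ", case$queried_variant$cdna)
  if (category == "OUT_OF_SCOPE") {
    return(paste0("The combination of evidence entered for the ", var,
                  " germline variant falls outside of the current parameters of the algorithm."))
  }
  if (category == "INCONCLUSIVE") {
    details <- paste0("[", codes, "] ", .code_meaning(codes), collapse = "; ")
    return(paste0("INCONCLUSIVE assessment for the ", var,
                  " germline variant: one or more key evidence is absent or adverse — ",
                  details, ". The required evidence is absent, so the variant cannot be assessed."))
  }
  body <- if (!is.null(note) && nzchar(note)) note else .code_meaning(codes)
  paste0(category, " assessment for the ", var, " germline variant in ",
         ifelse(case$cancer_type == "CRC", "colorectal", "endometrial"),
         " cancer [", paste(codes, collapse = ", "), "]: ", body, ".")
}

# ordered (question, answer) synopsis of a case, mirroring the questionnaire
case_synopsis <- function(case) {
  ans <- case_to_answers(case)
  qs <- schema_for(case$cancer_type)
  list(question = vapply(qs, function(q) q$prompt, character(1)),
       answer = unname(unlist(ans$answers)[vapply(qs, function(q) q$key,
                                                  character(1))]))
}

#' Assess a single evidence case
#'
#' The top-level decision tree. An invalid case raises an error listing the
#' violations. If any structural gate fails, the verdict is INCONCLUSIVE
#' carrying all failing gate codes; otherwise the per-gene stage decides
#' POSITIVE, NEUTRAL, INCONCLUSIVE (sporadic check) or OUT_OF_SCOPE. The
#' result is deterministic and total over valid inputs.
#'
#' @param case An [evidence_case()].
#' @param threshold PREMM5 threshold in percent.
#' @param validate Validate the case first (disable only for inputs already
#'   validated in bulk).
#' @param details Build the explanatory comment and synopsis (disable in
#'   bulk property runs where only category and codes are consumed).
#' @return An object of class `verdict`: list with `category`, `codes`,
#'   `comment` and `synopsis` (parallel `question`/`answer` vectors).
#' @examples
#' case <- evidence_case(
#'   cancer_type = "CRC",
#'   queried_variant = germline_finding("MSH2", "c.226C>T", "p.Q76*"),
#'   clinical = clinical_evidence(premm5_percent = 6.7),
#'   tumor = tumor_profile(
#'     braf_v600e = "NEGATIVE", msi = "MSI_HIGH",
#'     somatic_events = list(
#'       somatic_event("MSH2", "c.2334C>A (p.C778*)", inactivating = TRUE))),
#'   ihc = ihc_panel("INTACT", "LOST", "LOST", "INTACT"))
#' assess_case(case)$category
#' @export
assess_case <- function(case, threshold = 2.5, validate = TRUE,
                        details = TRUE) {
  if (validate) {
    v <- validate_case(case)
    if (length(v)) {
      stop("invalid evidence case:\n  ", paste(v, collapse = "\n  "),
           call. = FALSE)
    }
  }
  gates <- structural_gate_codes(case, threshold)
  if (length(gates)) {
    category <- "INCONCLUSIVE"
    codes <- gates
    note <- NULL
  } else {
    frag <- gene_stage_assess(case, threshold, check_gates = FALSE)
    category <- frag$category
    codes <- frag$codes
    note <- frag$note
  }
  structure(list(category = category,
                 codes = codes,
                 comment = if (details) verdict_comment(category, codes, case,
                                                        note),
                 synopsis = if (details) case_synopsis(case)),
            class = "verdict")
}

#' @export
print.verdict <- function(x, ...) {
  cat(sprintf("<verdict> %s%s\n", x$category,
              if (length(x$codes)) paste0(" [", paste(x$codes, collapse = ", "), "]")
              else ""))
  cat("  ", x$comment, "\n", sep = "")
  invisible(x)
}
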