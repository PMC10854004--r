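# Question schemas for the two cancer types, answer validation and the
# mapping between answer sets and evidence cases.
#
# The colorectal schema has 11 radio-button questions; the endometrial
# schema is the same minus the BRAF question (BRAF status in endometrial
# cancer is not a component of the decision tree). All questions are
# required; the cDNA of the variant under assessment is a separate free-text
# field (with an optional protein field).

IHC_ANSWER_LABELS <- c(
  NO_LOSS = "No loss of any MMR protein",
  MLH1_PMS2_LOSS = "Loss of MLH1 and PMS2",
  ISOLATED_MLH1 = "Isolated loss of MLH1",
  ISOLATED_PMS2 = "Isolated loss of PMS2",
  MSH2_MSH6_LOSS = "Loss of MSH2 and MSH6",
  ISOLATED_MSH2 = "Isolated loss of MSH2",
  ISOLATED_MSH6 = "Isolated loss of MSH6",
  MSH6_MLH1_PMS2_LOSS = "Loss of MLH1, PMS2, and MSH6",
  ALL_FOUR_LOSS = "Loss of all four MMR proteins",
  OTHER_COMBINATION = "Other combination of losses",
  NOT_ASSESSABLE = "Not all four proteins evaluable (equivocal, partial, or not performed)")

.schema_cache <- new.env(parent = emptyenv())

build_schema <- function(cancer_type) {
  q <- function(key, prompt, answers) {
    list(key = key, prompt = prompt, answers = answers)
  }
  qs <- list(
    q("vus_count", "How many germline VUS in MMR genes were identified?",
      c("1", "2 or more")),
    q("gene", "Which MMR gene harbors the VUS under assessment?", MMR_GENES),
    q("other_pathogenic",
      "Is another pathogenic or likely pathogenic germline MMR alteration present?",
      c("No", "Yes")),
    q("epcam", "Is an EPCAM 3' deletion present?", c("No", "Yes")),
    q("premm5", "Is the PREMM5 score at or above 2.5%?", c("Yes", "No")),
    q("amsterdam", "Are Amsterdam II criteria met?",
      c("Yes", "No", "Unknown")),
    q("braf", "What is the somatic BRAF p.V600E result?",
      c("Positive", "Negative", "Not tested")),
    q("methylation", "What is the MLH1 promoter methylation result?",
      c("Positive", "Negative", "Not tested")),
    q("second_hit",
      "Is somatic inactivation of the second allele of the queried gene documented?",
      c("Yes", "No")),
    q("msi", "What is the microsatellite instability status?",
      c("MSI-High", "MSS", "Not tested")),
    q("ihc", "What is the MMR IHC staining pattern?",
      unname(IHC_ANSWER_LABELS)))
  if (cancer_type == "EC") {
    qs <- Filter(function(x) x$key != "braf", qs)
  }
  qs
}

#' Questionnaire schema for a cancer type
#'
#' Ordered list of required radio-button questions: 11 for colorectal and
#' 10 for endometrial cancer (the endometrial schema omits the BRAF
#' question). Each question has a `key`, a `prompt` and a fixed ordered
#' answer set.
#'
#' @param cancer_type `"CRC"` or `"EC"`.
#' @return List of question records.
#' @export
schema_for <- function(cancer_type) {
  stopifnot(cancer_type %in% CANCER_TYPES)
  if (is.null(.schema_cache[[cancer_type]])) {
    .schema_cache[[cancer_type]] <- build_schema(cancer_type)
  }
  .schema_cache[[cancer_type]]
}

#' Build an answer set
#'
#' @param cancer_type `"CRC"` or `"EC"`.
#' @param answers Named list/character vector mapping question keys to chosen
#'   labels.
#' @param cdna Non-empty cDNA string of the variant under assessment.
#' @param protein Optional protein-change string.
#' @return An object of class `answer_set`.
#' @export
answer_set <- function(cancer_type, answers, cdna, protein = NA_character_) {
  structure(list(cancer_type = cancer_type, answers = as.list(answers),
                 cdna = cdna, protein = protein),
            class = "answer_set")
}

#' Validate an answer set against its schema
#'
#' Returns one message per violation: a missing question, a label outside a
#' question's answer set, or an empty cDNA. Entries outside the schema are
#' not processed.
#'
#' @param answers An [answer_set()].
#' @return Character vector of violations (empty if valid).
#' @export
validate_answers <- function(answers) {
  v <- character()
  if (!answers$cancer_type %in% CANCER_TYPES) {
    return(sprintf("cancer_type: must be one of {%s}",
                   paste(CANCER_TYPES, collapse = ", ")))
  }
  schema <- schema_for(answers$cancer_type)
  for (q in schema) {
    a <- answers$answers[[q$key]]
    if (is.null(a) || is.na(a)) {
      v <- c(v, sprintf("question '%s' (%s) is unanswered", q$key, q$prompt))
    } else if (!a %in% q$answers) {
      v <- c(v, sprintf("question '%s': answer label '%s' is outside the allowed set",
                        q$key, a))
    }
  }
  extra <- setdiff(names(answers$answers),
                   vapply(schema, function(q) q$key, character(1)))
  if (length(extra)) {
    v <- c(v, sprintf("unknown question key(s): %s",
                      paste(extra, collapse = ", ")))
  }
  if (!is.character(answers$cdna) || length(answers$cdna) != 1L ||
      is.na(answers$cdna) || !nzchar(answers$cdna)) {
    v <- c(v, "cdna: must be a non-empty string")
  }
  v
}

# canonical panel realizing each IHC answer label
.panel_for_pattern <- list(
  NO_LOSS = ihc_panel("INTACT", "INTACT", "INTACT", "INTACT"),
  MLH1_PMS2_LOSS = ihc_panel("LOST", "INTACT", "INTACT", "LOST"),
  ISOLATED_MLH1 = ihc_panel("LOST", "INTACT", "INTACT", "INTACT"),
  ISOLATED_PMS2 = ihc_panel("INTACT", "INTACT", "INTACT", "LOST"),
  MSH2_MSH6_LOSS = ihc_panel("INTACT", "LOST", "LOST", "INTACT"),
  ISOLATED_MSH2 = ihc_panel("INTACT", "LOST", "INTACT", "INTACT"),
  ISOLATED_MSH6 = ihc_panel("INTACT", "INTACT", "LOST", "INTACT"),
  MSH6_MLH1_PMS2_LOSS = ihc_panel("LOST", "INTACT", "LOST", "LOST"),
  ALL_FOUR_LOSS = ihc_panel("LOST", "LOST", "LOST", "LOST"),
  OTHER_COMBINATION = ihc_panel("LOST", "LOST", "INTACT", "INTACT"),
  NOT_ASSESSABLE = ihc_panel("INTACT", "INTACT", "EQUIVOCAL", "INTACT"))

.ternary_from_answer <- c(Positive = "POSITIVE", Negative = "NEGATIVE",
                          `Not tested` = "NOT_TESTED")
.msi_from_answer <- c(`MSI-High` = "MSI_HIGH", MSS = "MSS",
                      `Not tested` = "NOT_TESTED")

#' Map a validated answer set to an evidence case
#'
#' Deterministic, documented mapping; together with [case_to_answers()] it
#' round-trips (`case_to_answers(answers_to_case(a))` equals `a`). The
#' PREMM5 yes/no answer maps to a score exactly at the threshold (yes) or an
#' absent score (no); the IHC answer maps to the canonical panel realizing
#' the pattern; the second-hit answer sets the biallelic override.
#'
#' @param answers An [answer_set()] that passes [validate_answers()].
#' @param threshold PREMM5 threshold in percent.
#' @param check Validate the answers first (disable only for answer sets
#'   already validated in bulk, e.g. the enumerated space).
#' @return An [evidence_case()].
#' @export
answers_to_case <- function(answers, threshold = 2.5, check = TRUE) {
  if (check) {
    v <- validate_answers(answers)
    if (length(v)) {
      stop("invalid answers:\n  ", paste(v, collapse = "\n  "), call. = FALSE)
    }
  }
  a <- answers$answers
  pattern <- names(IHC_ANSWER_LABELS)[match(a$ihc, IHC_ANSWER_LABELS)]
  evidence_case(
    cancer_type = answers$cancer_type,
    germline_vus_count = if (identical(a$vus_count, "1")) 1L else 2L,
    queried_variant = germline_finding(a$gene, answers$cdna, answers$protein),
    other_pathogenic_mmr_germline = identical(a$other_pathogenic, "Yes"),
    epcam_3prime_deletion = identical(a$epcam, "Yes"),
    clinical = clinical_evidence(
      premm5_percent = if (identical(a$premm5, "Yes")) threshold else NA_real_,
      amsterdam_ii_met = switch(a$amsterdam, Yes = "TRUE", No = "FALSE",
                                Unknown = "UNKNOWN")),
    tumor = tumor_profile(
      braf_v600e = if (answers$cancer_type == "CRC") {
        .ternary_from_answer[[a$braf]]
      } else "NOT_TESTED",
      mlh1_promoter_methylation = .ternary_from_answer[[a$methylation]],
      msi = .msi_from_answer[[a$msi]],
      somatic_events = list(),
      biallelic_documented_override = identical(a$second_hit, "Yes")),
    ihc = .panel_for_pattern[[pattern]])
}

#' Map an evidence case back to questionnaire answers
#'
#' Inverse of [answers_to_case()] up to the canonical representation of each
#' answer (the IHC panel is reduced to its canonical pattern, the PREMM5
#' score to the threshold yes/no, somatic events to the second-hit yes/no).
#'
#' @param case An [evidence_case()].
#' @param threshold PREMM5 threshold in percent.
#' @return An [answer_set()].
#' @export
case_to_answers <- function(case, threshold = 2.5) {
  a <- list(
    vus_count = if (case$germline_vus_count == 1L) "1" else "2 or more",
    gene = case$queried_variant$gene,
    other_pathogenic = if (case$other_pathogenic_mmr_germline) "Yes" else "No",
    epcam = if (case$epcam_3prime_deletion) "Yes" else "No",
    premm5 = if (premm5_meets_threshold(case$clinical$premm5_percent, threshold))
      "Yes" else "No",
    amsterdam = switch(case$clinical$amsterdam_ii_met, `TRUE` = "Yes",
                       `FALSE` = "No", UNKNOWN = "Unknown"),
    braf = if (case$cancer_type == "CRC") {
      names(.ternary_from_answer)[
        match(case$tumor$braf_v600e, .ternary_from_answer)]
    },
    methylation = names(.ternary_from_answer)[
      match(case$tumor$mlh1_promoter_methylation, .ternary_from_answer)],
    second_hit = if (biallelic_documented(case$queried_variant$gene,
                                          case$tumor)) "Yes" else "No",
    msi = names(.msi_from_answer)[match(case$tumor$msi, .msi_from_answer)],
    ihc = unname(IHC_ANSWER_LABELS[[canonical_ihc_pattern(case$ihc)]]))
  a <- a[!vapply(a, is.null, logical(1))]  # EC has no braf entry
  answer_set(case$cancer_type, a, case$queried_variant$cdna,
             case$queried_variant$protein)
}

#' Export a schema as a machine-readable description
#'
#' @param cancer_type `"CRC"` or `"EC"`.
#' @return Data frame with columns `key`, `prompt`, `answers`
#'   (pipe-separated labels).
#' @export
schema_table <- function(cancer_type) {
  qs <- schema_for(cancer_type)
  data.frame(key = vapply(qs, function(q) q$key, character(1)),
             prompt = vapply(qs, function(q) q$prompt, character(1)),
             answers = vapply(qs, function(q) paste(q$answers, collapse = "|"),
                              character(1)))
}
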