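# Domain types and controlled vocabularies shared by all modules.
#
# Cases are plain named lists with S3 classes; every controlled-vocabulary
# field holds one label from a fixed set. Validation is collected by
# validate_case(), which returns messages rather than raising, so batch
# callers can report per-row problems.

#' Controlled vocabularies
#'
#' Fixed label sets used throughout the decision tree.
#'
#' @format Character vectors of allowed labels.
#' @name vocabularies
NULL

#' @rdname vocabularies
#' @export
MMR_GENES <- c("MLH1", "MSH2", "MSH6", "PMS2")

#' @rdname vocabularies
#' @export
CANCER_TYPES <- c("CRC", "EC")

#' @rdname vocabularies
#' @export
TERNARY_RESULTS <- c("POSITIVE", "NEGATIVE", "NOT_TESTED")

#' @rdname vocabularies
#' @export
MSI_STATUSES <- c("MSI_HIGH", "MSS", "NOT_TESTED")

#' @rdname vocabularies
#' @export
IHC_STATUSES <- c("LOST", "INTACT", "EQUIVOCAL", "PARTIAL_LOSS", "NOT_PERFORMED")

#' @rdname vocabularies
#' @export
SOMATIC_KINDS <- c("SNV_INDEL", "COPY_LOSS", "COPY_GAIN", "STRUCTURAL")

#' @rdname vocabularies
#' @export
AMSTERDAM_FLAGS <- c("TRUE", "FALSE", "UNKNOWN")

#' @rdname vocabularies
#' @export
GERMLINE_CLASSIFICATIONS <- c("VUS", "PATHOGENIC_OR_LP")

#' @rdname vocabularies
#' @export
VERDICT_CATEGORIES <- c("POSITIVE", "NEUTRAL", "INCONCLUSIVE", "OUT_OF_SCOPE")

#' Per-protein mismatch-repair immunohistochemistry panel
#'
#' Staining status for each of the four MMR proteins. Loss of nuclear
#' staining marks inactivation of the protein (or its heterodimer partner);
#' equivocal, partial or missing stains make the panel non-assessable for
#' the decision tree.
#'
#' @param mlh1,msh2,msh6,pms2 One of `IHC_STATUSES`.
#' @return An object of class `ihc_panel`.
#' @examples
#' ihc_panel(mlh1 = "LOST", msh2 = "INTACT", msh6 = "INTACT", pms2 = "LOST")
#' @export
ihc_panel <- function(mlh1 = "NOT_PERFORMED", msh2 = "NOT_PERFORMED",
                      msh6 = "NOT_PERFORMED", pms2 = "NOT_PERFORMED") {
  structure(list(mlh1 = mlh1, msh2 = msh2, msh6 = msh6, pms2 = pms2),
            class = "ihc_panel")
}

#' Germline finding under assessment
#'
#' The single germline MMR variant being queried. The HGVS-style cDNA string
#' is treated as an opaque identifier (checked for non-emptiness only).
#'
#' @param gene One of `MMR_GENES`.
#' @param cdna Non-empty coding-change string, e.g. `"c.226C>T"`.
#' @param protein Optional protein-change string, e.g. `"p.Q76*"`.
#' @param classification `"VUS"` (the engine's normal input) or
#'   `"PATHOGENIC_OR_LP"` (positive-control rows).
#' @return An object of class `germline_finding`.
#' @export
germline_finding <- function(gene, cdna, protein = NA_character_,
                             classification = "VUS") {
  structure(list(gene = gene, cdna = cdna, protein = protein,
                 classification = classification),
            class = "germline_finding")
}

#' Somatic event observed in the tumor
#'
#' @param gene One of `MMR_GENES`.
#' @param description Free text (a cDNA change, "single copy loss", ...).
#' @param kind One of `SOMATIC_KINDS`.
#' @param inactivating Annotator's assertion that the event inactivates the
#'   allele. `COPY_LOSS` events count as inactivating regardless of this flag.
#' @return An object of class `somatic_event`.
#' @export
somatic_event <- function(gene, description, kind = "SNV_INDEL",
                          inactivating = FALSE) {
  structure(list(gene = gene, description = description, kind = kind,
                 inactivating = isTRUE(inactivating)),
            class = "somatic_event")
}

#' Clinical evidence for Lynch syndrome
#'
#' @param premm5_percent PREMM5 risk score as a percentage in \[0, 100\], or
#'   `NA` when no score is available. The score itself is an input; it is not
#'   computed here.
#' @param amsterdam_ii_met `"TRUE"`, `"FALSE"` or `"UNKNOWN"`.
#' @return An object of class `clinical_evidence`.
#' @export
clinical_evidence <- function(premm5_percent = NA_real_,
                              amsterdam_ii_met = "UNKNOWN") {
  structure(list(premm5_percent = premm5_percent,
                 amsterdam_ii_met = amsterdam_ii_met),
            class = "clinical_evidence")
}

#' Tumor-derived molecular profile
#'
#' @param braf_v600e Somatic BRAF p.V600E result (`TERNARY_RESULTS`). Carried
#'   for endometrial cases but never consulted there.
#' @param mlh1_promoter_methylation MLH1 promoter methylation result
#'   (`TERNARY_RESULTS`).
#' @param msi One of `MSI_STATUSES`.
#' @param somatic_events List of [somatic_event()] objects (possibly empty).
#' @param biallelic_documented_override Optional logical; lets questionnaire
#'   users assert the second-hit question directly. `NA` means "not asserted".
#' @return An object of class `tumor_profile`.
#' @export
tumor_profile <- function(braf_v600e = "NOT_TESTED",
                          mlh1_promoter_methylation = "NOT_TESTED",
                          msi = "NOT_TESTED",
                          somatic_events = list(),
                          biallelic_documented_override = NA) {
  structure(list(braf_v600e = braf_v600e,
                 mlh1_promoter_methylation = mlh1_promoter_methylation,
                 msi = msi,
                 somatic_events = somatic_events,
                 biallelic_documented_override = biallelic_documented_override),
            class = "tumor_profile")
}

#' Assemble a single-case evidence bundle
#'
#' One patient/tumor evidence record: cancer type, germline findings,
#' clinical criteria, tumor molecular profile and IHC panel. This is the
#' input consumed by [assess_case()].
#'
#' @param cancer_type `"CRC"` or `"EC"`.
#' @param queried_variant A [germline_finding()] — the variant under
#'   assessment.
#' @param germline_vus_count Number of distinct germline MMR VUS reported
#'   (the decision tree requires exactly one).
#' @param other_pathogenic_mmr_germline Logical; another pathogenic/likely
#'   pathogenic germline MMR alteration is present.
#' @param epcam_3prime_deletion Logical; an EPCAM 3' deletion is present.
#' @param clinical A [clinical_evidence()].
#' @param tumor A [tumor_profile()].
#' @param ihc An [ihc_panel()].
#' @return An object of class `evidence_case`.
#' @examples
#' evidence_case(
#'   cancer_type = "CRC",
#'   queried_variant = germline_finding("MSH2", "c.226C>T", "p.Q76*"),
#'   clinical = clinical_evidence(premm5_percent = 6.7),
#'   tumor = tumor_profile(
#'     braf_v600e = "NEGATIVE", msi = "MSI_HIGH",
#'     somatic_events = list(
#'       somatic_event("MSH2", "c.2334C>A (p.C778*)", inactivating = TRUE))),
#'   ihc = ihc_panel("INTACT", "LOST", "LOST", "INTACT"))
#' @export
evidence_case <- function(cancer_type,
                          queried_variant,
                          germline_vus_count = 1L,
                          other_pathogenic_mmr_germline = FALSE,
                          epcam_3prime_deletion = FALSE,
                          clinical = clinical_evidence(),
                          tumor = tumor_profile(),
                          ihc = ihc_panel()) {
  structure(list(cancer_type = cancer_type,
                 germline_vus_count = as.integer(germline_vus_count),
                 queried_variant = queried_variant,
                 other_pathogenic_mmr_germline = isTRUE(other_pathogenic_mmr_germline),
                 epcam_3prime_deletion = isTRUE(epcam_3prime_deletion),
                 clinical = clinical,
                 tumor = tumor,
                 ihc = ihc),
            class = "evidence_case")
}

is_label <- function(x, vocab) {
  is.character(x) && length(x) == 1L && !is.na(x) && x %in% vocab
}

#' Validate an evidence case
#'
#' Checks every type invariant of the case model and returns one message per
#' violation; an empty character vector means the case is well formed.
#' Violations are returned, never raised, and each names the offending field.
#'
#' @param case An [evidence_case()].
#' @return Character vector of violation messages (empty if valid).
#' @export
validate_case <- function(case) {
  v <- character()
  if (!inherits(case, "evidence_case")) {
    return("case: not an evidence_case object")
  }
  if (!is_label(case$cancer_type, CANCER_TYPES)) {
    v <- c(v, sprintf("cancer_type: must be one of {%s}",
                      paste(CANCER_TYPES, collapse = ", ")))
  }
  if (!is.numeric(case$germline_vus_count) || length(case$germline_vus_count) != 1L ||
      is.na(case$germline_vus_count) || case$germline_vus_count < 0) {
    v <- c(v, "germline_vus_count: must be a non-negative integer")
  }
  qv <- case$queried_variant
  if (is.null(qv)) {
    v <- c(v, "queried_variant: missing")
  } else {
    if (!is_label(qv$gene, MMR_GENES)) {
      v <- c(v, sprintf("queried_variant.gene: must be one of {%s}",
                        paste(MMR_GENES, collapse = ", ")))
    }
    if (!is.character(qv$cdna) || length(qv$cdna) != 1L || is.na(qv$cdna) ||
        !nzchar(qv$cdna)) {
      v <- c(v, "queried_variant.cdna: must be a non-empty string")
    }
    if (!is_label(qv$classification, GERMLINE_CLASSIFICATIONS)) {
      v <- c(v, sprintf("queried_variant.classification: must be one of {%s}",
                        paste(GERMLINE_CLASSIFICATIONS, collapse = ", ")))
    }
    if (is.numeric(case$germline_vus_count) && length(case$germline_vus_count) == 1L &&
        !is.na(case$germline_vus_count) && case$germline_vus_count < 1) {
      v <- c(v, "germline_vus_count: must be >= 1 when a queried variant is present")
    }
  }
  cl <- case$clinical
  if (!is.na(cl$premm5_percent)) {
    if (!is.numeric(cl$premm5_percent) || cl$premm5_percent < 0 ||
        cl$premm5_percent > 100) {
      v <- c(v, "clinical.premm5_percent: must lie in [0, 100]")
    }
  }
  if (!is_label(cl$amsterdam_ii_met, AMSTERDAM_FLAGS)) {
    v <- c(v, "clinical.amsterdam_ii_met: must be TRUE, FALSE or UNKNOWN")
  }
  tm <- case$tumor
  if (!is_label(tm$braf_v600e, TERNARY_RESULTS)) {
    v <- c(v, "tumor.braf_v600e: invalid label")
  }
  if (!is_label(tm$mlh1_promoter_methylation, TERNARY_RESULTS)) {
    v <- c(v, "tumor.mlh1_promoter_methylation: invalid label")
  }
  if (!is_label(tm$msi, MSI_STATUSES)) {
    v <- c(v, "tumor.msi: invalid label")
  }
  for (ev in tm$somatic_events) {
    if (!is_label(ev$gene, MMR_GENES)) {
      v <- c(v, "tumor.somatic_events: event gene must be an MMR gene")
    }
    if (!is.character(ev$description) || !nzchar(ev$description)) {
      v <- c(v, "tumor.somatic_events: event description must be non-empty")
    }
    if (!is_label(ev$kind, SOMATIC_KINDS)) {
      v <- c(v, "tumor.somatic_events: event kind invalid")
    }
  }
  for (prot in c("mlh1", "msh2", "msh6", "pms2")) {
    if (!is_label(case$ihc[[prot]], IHC_STATUSES)) {
      v <- c(v, sprintf("ihc.%s: invalid label", prot))
    }
  }
  v
}

#' @export
print.evidence_case <- function(x, ...) {
  cat(sprintf("<evidence_case> %s | %s %s (%s)\n", x$cancer_type,
              x$queried_variant$gene, x$queried_variant$cdna,
              x$queried_variant$classification))
  cat(sprintf("  germline VUS count: %d; other pathogenic MMR: %s; EPCAM 3' del: %s\n",
              x$germline_vus_count, x$other_pathogenic_mmr_germline,
              x$epcam_3prime_deletion))
  cat(sprintf("  clinical: PREMM5 %s%%, Amsterdam II %s\n",
              ifelse(is.na(x$clinical$premm5_percent), "absent",
                     format(x$clinical$premm5_percent)),
              x$clinical$amsterdam_ii_met))
  cat(sprintf("  tumor: BRAF %s, MLH1 methylation %s, MSI %s, %d somatic event(s)\n",
              x$tumor$braf_v600e, x$tumor$mlh1_promoter_methylation,
              x$tumor$msi, length(x$tumor$somatic_events)))
  cat(sprintf("  IHC: MLH1 %s, MSH2 %s, MSH6 %s, PMS2 %s\n",
              x$ihc$mlh1, x$ihc$msh2, x$ihc$msh6, x$ihc$pms2))
  invisible(x)
}

# ---- flat serialization (one case per row of a tab-delimited batch file) ----

encode_somatic_events <- function(events) {
  if (length(events) == 0L) return("")
  paste(vapply(events, function(e) {
    paste(e$gene, e$description, e$kind,
          ifelse(isTRUE(e$inactivating), "TRUE", "FALSE"), sep = "|")
  }, character(1)), collapse = ";")
}

decode_somatic_events <- function(s) {
  if (is.na(s) || !nzchar(s)) return(list())
  lapply(strsplit(s, ";", fixed = TRUE)[[1]], function(part) {
    f <- strsplit(part, "|", fixed = TRUE)[[1]]
    if (length(f) != 4L) {
      stop("malformed somatic event field: ", part, call. = FALSE)
    }
    somatic_event(f[1], f[2], f[3], identical(f[4], "TRUE"))
  })
}

#' Flatten an evidence case to a named character row
#'
#' Column names equal field paths (e.g. `tumor.msi`); somatic events are
#' packed as `gene|description|kind|inactivating` separated by `;`. The
#' inverse is [row_to_case()].
#'
#' @param case An [evidence_case()].
#' @return Named character vector.
#' @export
case_to_row <- function(case) {
  c(cancer_type = case$cancer_type,
    germline_vus_count = as.character(case$germline_vus_count),
    queried_variant.gene = case$queried_variant$gene,
    queried_variant.cdna = case$queried_variant$cdna,
    queried_variant.protein = ifelse(is.na(case$queried_variant$protein), "",
                                     case$queried_variant$protein),
    queried_variant.classification = case$queried_variant$classification,
    other_pathogenic_mmr_germline = as.character(case$other_pathogenic_mmr_germline),
    epcam_3prime_deletion = as.character(case$epcam_3prime_deletion),
    clinical.premm5_percent = ifelse(is.na(case$clinical$premm5_percent), "",
                                     format(case$clinical$premm5_percent)),
    clinical.amsterdam_ii_met = case$clinical$amsterdam_ii_met,
    tumor.braf_v600e = case$tumor$braf_v600e,
    tumor.mlh1_promoter_methylation = case$tumor$mlh1_promoter_methylation,
    tumor.msi = case$tumor$msi,
    tumor.somatic_events = encode_somatic_events(case$tumor$somatic_events),
    tumor.biallelic_documented_override =
      ifelse(is.na(case$tumor$biallelic_documented_override), "",
             as.character(case$tumor$biallelic_documented_override)),
    ihc.mlh1 = case$ihc$mlh1, ihc.msh2 = case$ihc$msh2,
    ihc.msh6 = case$ihc$msh6, ihc.pms2 = case$ihc$pms2)
}

#' Rebuild an evidence case from a flat row
#'
#' @param row Named character vector or one-row data.frame with the columns
#'   written by [case_to_row()].
#' @return An [evidence_case()].
#' @export
row_to_case <- function(row) {
  if (is.data.frame(row)) row <- unlist(row[1, , drop = TRUE])
  row <- vapply(row, as.character, character(1))
  get_col <- function(name, default = "") {
    if (name %in% names(row) && !is.na(row[[name]])) row[[name]] else default
  }
  premm <- get_col("clinical.premm5_percent")
  override <- get_col("tumor.biallelic_documented_override")
  evidence_case(
    cancer_type = get_col("cancer_type"),
    germline_vus_count = as.integer(get_col("germline_vus_count", "1")),
    queried_variant = germline_finding(
      gene = get_col("queried_variant.gene"),
      cdna = get_col("queried_variant.cdna"),
      protein = {
        p <- get_col("queried_variant.protein")
        if (nzchar(p)) p else NA_character_
      },
      classification = get_col("queried_variant.classification", "VUS")),
    other_pathogenic_mmr_germline =
      identical(get_col("other_pathogenic_mmr_germline", "FALSE"), "TRUE"),
    epcam_3prime_deletion =
      identical(get_col("epcam_3prime_deletion", "FALSE"), "TRUE"),
    clinical = clinical_evidence(
      premm5_percent = if (nzchar(premm)) as.numeric(premm) else NA_real_,
      amsterdam_ii_met = get_col("clinical.amsterdam_ii_met", "UNKNOWN")),
    tumor = tumor_profile(
      braf_v600e = get_col("tumor.braf_v600e", "NOT_TESTED"),
      mlh1_promoter_methylation =
        get_col("tumor.mlh1_promoter_methylation", "NOT_TESTED"),
      msi = get_col("tumor.msi", "NOT_TESTED"),
      somatic_events = decode_somatic_events(get_col("tumor.somatic_events")),
      biallelic_documented_override =
        if (nzchar(override)) identical(override, "TRUE") else NA),
    ihc = ihc_panel(mlh1 = get_col("ihc.mlh1", "NOT_PERFORMED"),
                    msh2 = get_col("ihc.msh2", "NOT_PERFORMED"),
                    msh6 = get_col("ihc.msh6", "NOT_PERFORMED"),
                    pms2 = get_col("ihc.pms2", "NOT_PERFORMED")))
}

#' Read or write a batch of cases as a tab-delimited file
#'
#' One case per row; columns are the field paths of [case_to_row()].
#'
#' @param path File path.
#' @return `read_case_batch()` returns a list of [evidence_case()] objects.
#' @export
read_case_batch <- function(path) {
  df <- utils::read.delim(path, sep = "\t", colClasses = "character",
                          check.names = FALSE, na.strings = NULL)
  lapply(seq_len(nrow(df)), function(i) row_to_case(df[i, , drop = FALSE]))
}

#' @rdname read_case_batch
#' @param cases List of [evidence_case()] objects.
#' @export
write_case_batch <- function(cases, path) {
  rows <- do.call(rbind, lapply(cases, case_to_row))
  utils::write.table(as.data.frame(rows, check.names = FALSE), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Fixture-vocabulary normalization: the source control tables use these
# strings inconsistently ("MSI-S", "None", "N/A", "Neg", "hypermethylation").
normalize_msi <- function(x) {
  x <- trimws(x)
  if (x %in% c("MSI-High", "MSI-H", "MSI_HIGH")) return("MSI_HIGH")
  if (x %in% c("MSI-S", "MSS")) return("MSS")
  if (x %in% c("", "None", "N/A", "NA", "NOT_TESTED")) return("NOT_TESTED")
  stop("unrecognized MSI label: ", x, call. = FALSE)
}

normalize_ternary <- function(x) {
  x <- trimws(x)
  if (x %in% c("Neg", "Negative", "NEGATIVE", "Unmethylated")) return("NEGATIVE")
  if (x %in% c("Positive", "POSITIVE") || grepl("hyper ?methylation", x)) {
    return("POSITIVE")
  }
  if (x %in% c("", "None", "N/A", "NA", "NOT_TESTED")) return("NOT_TESTED")
  stop("unrecognized test-result label: ", x, call. = FALSE)
}
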