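# Packaged positive-control table (52 cases transcribed from the published
# control cohort), its loader/normalizer, the cohort evaluation harness, and
# generators for exhaustive and randomized engine testing.
#
# The printed code IDs are retained verbatim for provenance but never drive
# pass/fail logic; the expected class is POSITIVE exactly when the printed
# code belongs to families II-V, and the loader enforces that invariant.

#' Path of the packaged positive-control table
#' @return File path of the installed fixture.
#' @export
control_table_path <- function() {
  system.file("extdata", "positive_controls.tsv", package = "lynchtree",
              mustWork = TRUE)
}

parse_premm <- function(x, subject) {
  raw <- gsub("[][%> ]", "", x)
  val <- suppressWarnings(as.numeric(raw))
  if (is.na(val)) {
    stop("subject ", subject, ": malformed PREMM score '", x, "'",
         call. = FALSE)
  }
  val
}

code_family <- function(printed_code) {
  first <- regmatches(printed_code, regexpr("^[IVX]+", printed_code))
  if (!length(first)) return(NA_character_)
  first
}

#' Load the positive-control table
#'
#' Parses and normalizes the packaged 52-row fixture (or a file in the same
#' layout): PREMM scores are stripped of decoration (`%`, `>`, brackets),
#' test results and MSI labels are normalized to the controlled
#' vocabularies, an absent BRAF cell becomes NOT_TESTED, and somatic events
#' are unpacked. A malformed row raises an error naming its subject.
#'
#' @param path Fixture path; defaults to the packaged table.
#' @return List of `control_record` objects.
#' @export
load_control_table <- function(path = control_table_path()) {
  df <- utils::read.delim(path, sep = "\t", colClasses = "character",
                          check.names = FALSE, na.strings = NULL)
  if (anyDuplicated(df$subject_id)) {
    stop("duplicate subject ids in control table", call. = FALSE)
  }
  lapply(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    sid <- r$subject_id
    rec <- tryCatch({
      printed <- r$printed_code
      fam <- code_family(printed)
      expected <- r$expected_class
      derived <- if (!is.na(fam) && fam %in% c("II", "III", "IV", "V")) {
        "POSITIVE"
      } else "NON_POSITIVE"
      if (!identical(expected, derived)) {
        stop("expected_class '", expected,
             "' inconsistent with printed code family '", printed, "'")
      }
      structure(list(
        subject_id = as.integer(sid),
        cancer_type = r$cancer_type,
        premm5_percent = parse_premm(r$premm5_percent, sid),
        germline = germline_finding(
          gene = r$gene, cdna = r$cdna,
          protein = if (nzchar(r$protein)) r$protein else NA_character_,
          classification = "PATHOGENIC_OR_LP"),
        braf = normalize_ternary(r$braf),
        methylation = normalize_ternary(r$methylation),
        msi = normalize_msi(r$msi),
        ihc = ihc_panel(r$ihc_mlh1, r$ihc_msh2, r$ihc_msh6, r$ihc_pms2),
        ihc_verbatim = r$ihc_verbatim,
        somatic_events = decode_somatic_events(r$somatic_events),
        printed_code = printed,
        expected_class = expected,
        reported_organ = r$reported_organ),
        class = "control_record")
    }, error = function(e) {
      stop("control table row for subject ", sid, ": ", conditionMessage(e),
           call. = FALSE)
    })
    rec
  })
}

#' Turn a control record into an engine input
#'
#' The control's pathogenic variant plays the role of the queried VUS
#' (positive controls probe whether the engine recovers known pathogenic
#' alleles). The case carries exactly one germline finding, no other
#' pathogenic MMR alteration, no EPCAM deletion, and an unknown Amsterdam
#' flag (the control tables print only the PREMM score).
#'
#' @param record A `control_record` from [load_control_table()].
#' @return An [evidence_case()].
#' @export
control_to_case <- function(record) {
  evidence_case(
    cancer_type = record$cancer_type,
    germline_vus_count = 1L,
    queried_variant = record$germline,
    other_pathogenic_mmr_germline = FALSE,
    epcam_3prime_deletion = FALSE,
    clinical = clinical_evidence(premm5_percent = record$premm5_percent,
                                 amsterdam_ii_met = "UNKNOWN"),
    tumor = tumor_profile(braf_v600e = record$braf,
                          mlh1_promoter_methylation = record$methylation,
                          msi = record$msi,
                          somatic_events = record$somatic_events),
    ihc = record$ihc)
}

#' Run the engine over the control cohort
#'
#' Assesses every record and summarizes: total, POSITIVE and non-POSITIVE
#' counts, verdicts per evidence-code family, per-code counts of the flag
#' codes, and any mismatches against each record's expected class
#' (expected POSITIVE means the verdict category is POSITIVE; anything else
#' counts as non-POSITIVE).
#'
#' @param records List from [load_control_table()].
#' @param threshold PREMM5 threshold in percent.
#' @return An `evaluation_summary` list.
#' @export
evaluate_controls <- function(records, threshold = 2.5) {
  n <- length(records)
  categories <- character(n)
  codes_list <- vector("list", n)
  mismatches <- list()
  for (i in seq_len(n)) {
    rec <- records[[i]]
    verdict <- assess_case(control_to_case(rec), threshold = threshold)
    categories[i] <- verdict$category
    codes_list[[i]] <- verdict$codes
    got <- if (verdict$category == "POSITIVE") "POSITIVE" else "NON_POSITIVE"
    if (!identical(got, rec$expected_class)) {
      mismatches[[length(mismatches) + 1L]] <- data.frame(
        subject_id = rec$subject_id, expected = rec$expected_class,
        got = verdict$category)
    }
  }
  all_codes <- unlist(codes_list)
  fams <- sub("^(CRC|EC) ([IVX]+)-.*$", "\\2", all_codes)
  list(total = n,
       positive = sum(categories == "POSITIVE"),
       non_positive = sum(categories != "POSITIVE"),
       categories = table(categories),
       per_code_family = if (length(fams)) table(fams) else table(character()),
       per_code = if (length(all_codes)) table(all_codes) else table(character()),
       mismatches = if (length(mismatches)) do.call(rbind, mismatches)
                    else data.frame(subject_id = integer(),
                                    expected = character(),
                                    got = character()))
}

#' Enumerate the full questionnaire answer space
#'
#' Cartesian product of every question's answer set for a cancer type, in a
#' fixed deterministic order, with a placeholder cDNA. The space is finite
#' (114,048 colorectal and 38,016 endometrial combinations), so engine
#' properties can be checked by brute force rather than sampling.
#'
#' @param cancer_type `"CRC"` or `"EC"`.
#' @return Data frame; one column per question key, one row per combination.
#' @export
enumerate_answer_space <- function(cancer_type) {
  qs <- schema_for(cancer_type)
  grid <- expand.grid(lapply(qs, function(q) q$answers),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  names(grid) <- vapply(qs, function(q) q$key, character(1))
  grid
}

#' Build the answer set for one row of the enumerated space
#'
#' @param cancer_type `"CRC"` or `"EC"`.
#' @param row One-row slice (or named list) of [enumerate_answer_space()].
#' @param cdna Placeholder cDNA.
#' @return An [answer_set()].
#' @export
grid_answer_set <- function(cancer_type, row, cdna = "c.1A>G") {
  answer_set(cancer_type, as.list(row), cdna = cdna)
}

#' Assess every combination of the enumerated answer space
#'
#' Runs the full decision tree over the cartesian product of the
#' questionnaire answers for a cancer type and returns one verdict per
#' combination (category plus semicolon-joined codes), in the deterministic
#' order of [enumerate_answer_space()]. The answer columns are validated
#' once against the schema up front; each combination is then mapped to its
#' evidence case and assessed individually. Used by the brute-force
#' property checks, where flips of a single answer become index lookups
#' into this table.
#'
#' @param cancer_type `"CRC"` or `"EC"`.
#' @param threshold PREMM5 threshold in percent.
#' @param braf Optional label overriding the case-level BRAF field after
#'   construction (only meaningful for EC, whose schema has no BRAF
#'   question; used to verify that EC verdicts ignore BRAF).
#' @return Data frame with columns `category` and `codes`, with the answer
#'   grid attached as attribute `"grid"`.
#' @export
assess_answer_space <- function(cancer_type, threshold = 2.5, braf = NULL) {
  grid <- enumerate_answer_space(cancer_type)
  qs <- schema_for(cancer_type)
  for (q in qs) {  # one vectorized validation pass over each column
    bad <- !grid[[q$key]] %in% q$answers
    if (any(bad)) stop("enumerated answers outside schema for ", q$key)
  }
  n <- nrow(grid)
  cols <- as.list(grid)
  keys <- names(cols)
  category <- character(n)
  codes <- character(n)
  template <- answer_set(cancer_type, list(), cdna = "c.1A>G")
  for (i in seq_len(n)) {
    a <- lapply(cols, function(col) col[[i]])
    template$answers <- a
    case <- answers_to_case(template, threshold, check = FALSE)
    if (!is.null(braf)) case$tumor$braf_v600e <- braf
    v <- assess_case(case, threshold, validate = FALSE, details = FALSE)
    category[i] <- v$category
    codes[i] <- paste(v$codes, collapse = ";")
  }
  out <- data.frame(category = category, codes = codes)
  attr(out, "grid") <- grid
  out
}

#' Generate reproducible random evidence cases
#'
#' Samples valid cases for stress testing. `weights` biases
#' evidence-presence probabilities (probability that the PREMM score is
#' present, that a somatic second hit exists, that each tumor test was
#' performed). The RNG state is restored afterwards.
#'
#' @param n Number of cases (>= 0).
#' @param seed Integer seed; the same seed always yields the same list.
#' @param weights Named list of probabilities in \[0, 1\]:
#'   `premm_present`, `second_hit`, `test_performed`.
#' @return List of `n` valid [evidence_case()] objects.
#' @export
generate_random_cases <- function(n, seed = 1L,
                                  weights = list(premm_present = 0.8,
                                                 second_hit = 0.5,
                                                 test_performed = 0.7)) {
  stopifnot(n >= 0)
  for (w in c("premm_present", "second_hit", "test_performed")) {
    p <- weights[[w]]
    if (is.null(p) || !is.numeric(p) || p < 0 || p > 1) {
      stop("invalid weight '", w, "': must be a probability in [0, 1]",
           call. = FALSE)
    }
  }
  if (n == 0L) return(list())
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(seed)
  ternary_or_nt <- function() {
    if (stats::runif(1) < weights$test_performed) {
      sample(c("POSITIVE", "NEGATIVE"), 1L)
    } else "NOT_TESTED"
  }
  lapply(seq_len(n), function(i) {
    gene <- sample(MMR_GENES, 1L)
    has_hit <- stats::runif(1) < weights$second_hit
    evidence_case(
      cancer_type = sample(CANCER_TYPES, 1L),
      germline_vus_count = sample(1:2, 1L, prob = c(0.9, 0.1)),
      queried_variant = germline_finding(
        gene, sprintf("c.%dA>G", sample.int(3000, 1L))),
      other_pathogenic_mmr_germline = stats::runif(1) < 0.05,
      epcam_3prime_deletion = stats::runif(1) < 0.05,
      clinical = clinical_evidence(
        premm5_percent = if (stats::runif(1) < weights$premm_present) {
          min(100, round(stats::rexp(1, rate = 1 / 6), 2))
        } else NA_real_,
        amsterdam_ii_met = sample(AMSTERDAM_FLAGS, 1L,
                                  prob = c(0.2, 0.3, 0.5))),
      tumor = tumor_profile(
        braf_v600e = ternary_or_nt(),
        mlh1_promoter_methylation = ternary_or_nt(),
        msi = if (stats::runif(1) < weights$test_performed) {
          sample(c("MSI_HIGH", "MSS"), 1L)
        } else "NOT_TESTED",
        somatic_events = if (has_hit) {
          list(somatic_event(gene, sprintf("c.%ddel", sample.int(3000, 1L)),
                             "SNV_INDEL", inactivating = TRUE))
        } else list()),
      ihc = .panel_for_pattern[[sample(names(.panel_for_pattern), 1L)]])
  })
}
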