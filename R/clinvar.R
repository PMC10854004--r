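# Evidence-synopsis export for ClinVar submission.
#
# Only POSITIVE and NEUTRAL verdicts may be exported. The file is a UTF-8,
# tab-delimited, LF-terminated spreadsheet: one header row and one value row
# with the ClinVar-prompted fields, followed by the question/answer synopsis
# block. Nothing is ever sent anywhere; the file stays local.

#' Build a ClinVar submission record
#'
#' Populates the fields ClinVar prompts for (assertion method, assertion
#' method citation, citation URL, comment on clinical significance) plus the
#' download date and algorithm version, the variant identity, and the full
#' question/answer synopsis. Refused for INCONCLUSIVE and OUT_OF_SCOPE
#' verdicts — export is offered only for POSITIVE and NEUTRAL cases.
#'
#' @param case The assessed [evidence_case()].
#' @param verdict The [assess_case()] verdict.
#' @param version Algorithm version string.
#' @param date Download date (`Date` or ISO-8601 string).
#' @param config Optional [run_config()] overriding the assertion/citation
#'   fields.
#' @return An object of class `submission_record`.
#' @export
build_submission <- function(case, verdict, version = "1.0.0",
                             date = Sys.Date(), config = run_config()) {
  if (!verdict$category %in% c("POSITIVE", "NEUTRAL")) {
    stop("export only for POSITIVE and NEUTRAL assessments; got ",
         verdict$category, call. = FALSE)
  }
  structure(list(
    assertion_method = config$assertion_method,
    assertion_method_citation = config$assertion_method_citation,
    citation_url = config$citation_url,
    comment_on_clinical_significance = verdict$comment,
    download_date = format(as.Date(date), "%Y-%m-%d"),
    algorithm_version = version,
    gene = case$queried_variant$gene,
    cdna = case$queried_variant$cdna,
    protein = case$queried_variant$protein,
    category = verdict$category,
    synopsis = verdict$synopsis),
    class = "submission_record")
}

sanitize_filename_part <- function(x) {
  gsub("[^A-Za-z0-9._-]", "_", x)
}

#' File-name tag for a submission record
#'
#' `<gene>_<cdna>[_<protein>]` with characters unsafe for file names
#' replaced by underscores.
#'
#' @param record A [build_submission()] record.
#' @return Character scalar (no extension).
#' @export
submission_file_tag <- function(record) {
  parts <- c(record$gene, record$cdna)
  if (!is.na(record$protein) && nzchar(record$protein)) {
    parts <- c(parts, record$protein)
  }
  paste(vapply(parts, sanitize_filename_part, character(1)), collapse = "_")
}

#' Write a submission record to a tab-delimited file
#'
#' Writes one header row and one value row of the ClinVar fields, a blank
#' line, then the question/answer synopsis block. When `path` is a
#' directory, the file name is the variant tag from
#' [submission_file_tag()] plus `.tsv`. Output is byte-deterministic for a
#' fixed record (UTF-8, LF endings).
#'
#' @param record A [build_submission()] record.
#' @param path Target file path, or an existing directory.
#' @return The written file path, invisibly.
#' @export
write_submission <- function(record, path) {
  if (dir.exists(path)) {
    path <- file.path(path, paste0(submission_file_tag(record), ".tsv"))
  }
  fields <- c("assertion_method", "assertion_method_citation", "citation_url",
              "comment_on_clinical_significance", "download_date",
              "algorithm_version", "gene", "cdna", "protein", "category")
  values <- vapply(fields, function(f) {
    v <- record[[f]]
    if (is.null(v) || is.na(v)) "" else as.character(v)
  }, character(1))
  if (is.na(record$protein) || !nzchar(record$protein)) {
    fields <- setdiff(fields, "protein")
    values <- values[fields]
  }
  lines <- c(paste(fields, collapse = "\t"),
             paste(values, collapse = "\t"),
             "",
             "question\tanswer",
             paste(record$synopsis$question, record$synopsis$answer,
                   sep = "\t"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read back a written submission file
#'
#' Inverse of [write_submission()]; recovers every field of the record.
#'
#' @param path File written by [write_submission()].
#' @return A `submission_record`.
#' @export
read_submission <- function(path) {
  lines <- readLines(path)
  blank <- which(lines == "")[1]
  fields <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  values <- strsplit(lines[2], "\t", fixed = TRUE)[[1]]
  length(values) <- length(fields)  # trailing empty cells
  rec <- as.list(values)
  names(rec) <- fields
  if (is.null(rec$protein) || is.na(rec$protein)) rec$protein <- NA_character_
  qa <- lines[(blank + 2):length(lines)]
  qa_split <- strsplit(qa, "\t", fixed = TRUE)
  rec$synopsis <- list(
    question = vapply(qa_split, `[`, character(1), 1),
    answer = vapply(qa_split, `[`, character(1), 2))
  structure(rec, class = "submission_record")
}
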