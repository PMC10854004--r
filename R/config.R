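# Run configuration: thresholds, version string, Amsterdam cancer set and
# the citation fields used by the ClinVar exporter.

#' Run configuration
#'
#' @param premm5_threshold PREMM5 threshold in percent, in (0, 100].
#' @param algorithm_version Version string recorded in exports.
#' @param ls_cancer_labels Cancer labels counted as Lynch syndrome-associated
#'   for Amsterdam II.
#' @param assertion_method,assertion_method_citation,citation_url Fields for
#'   the ClinVar submission synopsis.
#' @return An object of class `run_config`.
#' @export
run_config <- function(premm5_threshold = 2.5,
                       algorithm_version = "1.0.0",
                       ls_cancer_labels = LS_CANCER_LABELS,
                       assertion_method = "Integrated germline-tumor decision tree for MMR VUS in suspected Lynch syndrome",
                       assertion_method_citation = "doi:10.3389/fonc.2023.1284690",
                       citation_url = "https://doi.org/10.3389/fonc.2023.1284690") {
  stopifnot(is.numeric(premm5_threshold), premm5_threshold > 0,
            premm5_threshold <= 100)
  structure(list(premm5_threshold = premm5_threshold,
                 algorithm_version = algorithm_version,
                 ls_cancer_labels = ls_cancer_labels,
                 assertion_method = assertion_method,
                 assertion_method_citation = assertion_method_citation,
                 citation_url = citation_url),
            class = "run_config")
}

#' Read a configuration file
#'
#' Simple key: value text (YAML subset); unknown keys are rejected.
#'
#' @param path Config file path.
#' @return A [run_config()].
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  extra <- setdiff(names(vals), known)
  if (length(extra)) {
    stop("unknown config key(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  do.call(run_config, vals)
}
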