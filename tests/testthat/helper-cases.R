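# Builders for representative cases and pedigrees used across tests.

# fully evidenced CRC case for an MSH2 VUS (POSITIVE under the tree)
full_msh2_crc_case <- function(...) {
  defaults <- list(
    cancer_type = "CRC",
    queried_variant = germline_finding("MSH2", "c.226C>T", "p.Q76*"),
    clinical = clinical_evidence(premm5_percent = 6.7),
    tumor = tumor_profile(
      braf_v600e = "NEGATIVE",
      mlh1_promoter_methylation = "NEGATIVE",
      msi = "MSI_HIGH",
      somatic_events = list(
        somatic_event("MSH2", "c.2334C>A (p.C778*)", inactivating = TRUE))),
    ihc = ihc_panel("INTACT", "LOST", "LOST", "INTACT"))
  overrides <- list(...)
  defaults[names(overrides)] <- overrides
  do.call(evidence_case, defaults)
}

# fully evidenced CRC case for an MLH1 VUS
full_mlh1_crc_case <- function(...) {
  defaults <- list(
    cancer_type = "CRC",
    queried_variant = germline_finding("MLH1", "c.116+2T>G"),
    clinical = clinical_evidence(premm5_percent = 5.7),
    tumor = tumor_profile(
      braf_v600e = "NEGATIVE",
      mlh1_promoter_methylation = "NEGATIVE",
      msi = "MSI_HIGH",
      somatic_events = list(
        somatic_event("MLH1", "single-copy loss", "COPY_LOSS"))),
    ihc = ihc_panel("LOST", "INTACT", "INTACT", "LOST"))
  overrides <- list(...)
  defaults[names(overrides)] <- overrides
  do.call(evidence_case, defaults)
}

# three-generation pedigree meeting every Amsterdam II clause:
# grandmother (colorectal at 45), her two children, one affected grandchild
amsterdam_positive_pedigree <- function(fap_excluded = TRUE,
                                        proband_dx_age = 45) {
  pedigree(
    proband_id = "proband",
    members = list(
      relative("gm", generation = -2L,
               diagnoses = data.frame(cancer = "colorectal",
                                      age = proband_dx_age)),
      relative("gf", generation = -2L),
      relative("mother", mother_id = "gm", father_id = "gf",
               generation = -1L,
               diagnoses = data.frame(cancer = "endometrial", age = 52)),
      relative("uncle", mother_id = "gm", father_id = "gf",
               generation = -1L,
               diagnoses = data.frame(cancer = "colorectal", age = 55)),
      relative("father", generation = -1L),
      relative("proband", mother_id = "mother", father_id = "father",
               generation = 0L)),
    fap_excluded = fap_excluded)
}

# spec-style pedigree: affected parent + two affected children
parent_two_children_pedigree <- function(parent_age = 45,
                                         child_ages = c(52, 55),
                                         fap_excluded = TRUE) {
  pedigree(
    proband_id = "c1",
    members = list(
      relative("p", generation = -1L,
               diagnoses = data.frame(cancer = "colorectal",
                                      age = parent_age)),
      relative("s", generation = -1L),
      relative("c1", mother_id = "p", father_id = "s", generation = 0L,
               diagnoses = data.frame(cancer = "endometrial",
                                      age = child_ages[1])),
      relative("c2", mother_id = "p", father_id = "s", generation = 0L,
               diagnoses = data.frame(cancer = "colorectal",
                                      age = child_ages[2]))),
    fap_excluded = fap_excluded)
}

# answer set covering every CRC question (a POSITIVE MSH2 scenario)
full_crc_answers <- function(...) {
  a <- list(vus_count = "1", gene = "MSH2", other_pathogenic = "No",
            epcam = "No", premm5 = "Yes", amsterdam = "Unknown",
            braf = "Negative", methylation = "Negative",
            second_hit = "Yes", msi = "MSI-High",
            ihc = "Loss of MSH2 and MSH6")
  a <- utils::modifyList(a, list(...))
  answer_set("CRC", a, cdna = "c.226C>T", protein = "p.Q76*")
}
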