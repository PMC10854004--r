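# Clinical-criteria evaluators: the PREMM5 threshold rule and a
# pedigree-based Amsterdam II checker.

#' Lynch syndrome-associated cancers for Amsterdam II
#'
#' Default tumor set counted as Lynch syndrome-associated when evaluating
#' Amsterdam II; configurable in [amsterdam_ii_met()].
#' @export
LS_CANCER_LABELS <- c("colorectal", "endometrial", "small bowel",
                      "ureter", "renal pelvis")

#' PREMM5 threshold rule
#'
#' The PREMM5 model gives a percent probability of carrying an MMR gene
#' mutation; scores at or above the threshold (2.5% by default, inclusive)
#' qualify as meeting clinical criteria. The score is an input — it is not
#' computed here. An absent score never satisfies the threshold.
#'
#' @param premm5_percent Numeric score in percent, or `NA`/`NULL` if absent.
#' @param threshold Threshold in percent, in (0, 100].
#' @return Logical.
#' @examples
#' premm5_meets_threshold(2.5)  # TRUE (inclusive bound)
#' premm5_meets_threshold(2.4)  # FALSE
#' premm5_meets_threshold(NA)   # FALSE
#' @export
premm5_meets_threshold <- function(premm5_percent, threshold = 2.5) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L,
            threshold > 0, threshold <= 100)
  if (is.null(premm5_percent) || length(premm5_percent) == 0L ||
      is.na(premm5_percent)) {
    return(FALSE)
  }
  premm5_percent >= threshold
}

#' Build a relative record for a pedigree
#'
#' @param id Unique label.
#' @param mother_id,father_id Optional labels of parents (must exist in the
#'   pedigree).
#' @param generation Integer; proband = 0, parents = -1, children = +1, ...
#' @param diagnoses Data frame with columns `cancer` (label) and `age`
#'   (age at diagnosis in years), or `NULL`.
#' @return An object of class `relative`.
#' @export
relative <- function(id, mother_id = NA_character_, father_id = NA_character_,
                     generation = 0L, diagnoses = NULL) {
  if (is.null(diagnoses)) {
    diagnoses <- data.frame(cancer = character(), age = numeric())
  }
  structure(list(id = as.character(id),
                 mother_id = as.character(mother_id),
                 father_id = as.character(father_id),
                 generation = as.integer(generation),
                 diagnoses = diagnoses),
            class = "relative")
}

#' Build a pedigree
#'
#' @param proband_id Label of the proband; must be among `members`.
#' @param members List of [relative()] records.
#' @param fap_excluded Logical; familial adenomatous polyposis has been
#'   excluded (required by Amsterdam II when colorectal cancer is present).
#' @return An object of class `pedigree`.
#' @export
pedigree <- function(proband_id, members, fap_excluded = FALSE) {
  ids <- vapply(members, function(m) m$id, character(1))
  if (anyDuplicated(ids)) stop("duplicate relative ids", call. = FALSE)
  if (!proband_id %in% ids) {
    stop("proband_id not among pedigree members", call. = FALSE)
  }
  for (m in members) {
    for (p in c(m$mother_id, m$father_id)) {
      if (!is.na(p) && !p %in% ids) {
        stop("parent id not in pedigree: ", p, call. = FALSE)
      }
    }
    if (any(m$diagnoses$age <= 0)) {
      stop("diagnosis ages must be positive (relative ", m$id, ")",
           call. = FALSE)
    }
  }
  ped <- structure(list(proband_id = proband_id, members = members,
                        fap_excluded = isTRUE(fap_excluded)),
                   class = "pedigree")
  check_acyclic(ped)
  ped
}

member_by_id <- function(ped, id) {
  for (m in ped$members) if (m$id == id) return(m)
  stop("unknown relative id: ", id, call. = FALSE)
}

check_acyclic <- function(ped) {
  # follow parent links from every member; a revisit along one walk = cycle
  for (m in ped$members) {
    seen <- character()
    frontier <- m$id
    while (length(frontier)) {
      if (any(frontier %in% seen)) {
        stop("cyclic parent links in pedigree", call. = FALSE)
      }
      seen <- c(seen, frontier)
      frontier <- unlist(lapply(frontier, function(id) {
        mm <- member_by_id(ped, id)
        p <- c(mm$mother_id, mm$father_id)
        p[!is.na(p)]
      }))
    }
  }
  invisible(TRUE)
}

pedigree_graph <- function(ped) {
  ids <- vapply(ped$members, function(m) m$id, character(1))
  from <- character(); to <- character()
  for (m in ped$members) {
    for (p in c(m$mother_id, m$father_id)) {
      if (!is.na(p)) { from <- c(from, m$id); to <- c(to, p) }
    }
  }
  # full siblings (both parents shared and known) are first degree: add a
  # direct edge so composed paths (uncle = parent + sibling) get the
  # conventional genetic degree
  n <- length(ped$members)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        a <- ped$members[[i]]; b <- ped$members[[j]]
        if (!is.na(a$mother_id) && !is.na(a$father_id) &&
            identical(a$mother_id, b$mother_id) &&
            identical(a$father_id, b$father_id)) {
          from <- c(from, a$id); to <- c(to, b$id)
        }
      }
    }
  }
  g <- igraph::make_empty_graph(directed = FALSE) +
    igraph::vertices(ids)
  if (length(from)) {
    g <- igraph::add_edges(g, rbind(from, to))
  }
  g
}

#' Degree of relationship between two pedigree members
#'
#' Degree 1 for parent/child and for full siblings (both parents shared);
#' otherwise the shortest path through parent links, with the full-sibling
#' shortcut composable (so an uncle/aunt through a full sibling of a parent
#' is degree 2, a half-sibling degree 2, a grandparent degree 2).
#'
#' @param ped A [pedigree()].
#' @param a,b Member ids.
#' @return A non-negative integer, or `Inf` if unrelated (`a == b` gives 0).
#' @export
relationship_degree <- function(ped, a, b) {
  member_by_id(ped, a); member_by_id(ped, b)  # errors name unknown ids
  if (identical(a, b)) return(0L)
  g <- pedigree_graph(ped)
  d <- igraph::distances(g, v = a, to = b)[1, 1]
  if (is.infinite(d)) Inf else as.integer(d)
}

#' Evaluate Amsterdam II criteria on a pedigree
#'
#' Amsterdam II is met when some set of three or more members affected by a
#' Lynch syndrome-associated cancer satisfies all of: one member is a
#' first-degree relative of (at least) two of the others; the members'
#' generations include two successive values; at least one qualifying
#' diagnosis was made before age 50 (strictly); and, when any qualifying
#' diagnosis in the set is colorectal, familial adenomatous polyposis has
#' been excluded. The proband counts among the relatives. The search is
#' exhaustive over affected-member subsets.
#'
#' @param ped A [pedigree()].
#' @param ls_cancer_labels Cancer labels counted as Lynch syndrome-associated.
#' @param include_proband Whether the proband's own diagnoses count.
#' @return List with `met` (logical) and `reasons` (character vector of
#'   failed clauses; empty when met).
#' @export
amsterdam_ii_met <- function(ped, ls_cancer_labels = LS_CANCER_LABELS,
                             include_proband = TRUE) {
  affected <- Filter(function(m) {
    if (!include_proband && m$id == ped$proband_id) return(FALSE)
    any(tolower(m$diagnoses$cancer) %in% tolower(ls_cancer_labels))
  }, ped$members)
  ls_dx <- function(m) {
    m$diagnoses[tolower(m$diagnoses$cancer) %in% tolower(ls_cancer_labels), ,
                drop = FALSE]
  }
  if (length(affected) < 3L) {
    return(list(met = FALSE,
                reasons = "fewer than three affected relatives with a Lynch syndrome-associated cancer"))
  }
  ids <- vapply(affected, function(m) m$id, character(1))
  deg <- outer(ids, ids, Vectorize(function(x, y) relationship_degree(ped, x, y)))
  subset_ok <- function(idx) {
    gens <- sort(unique(vapply(affected[idx], function(m) m$generation,
                               integer(1))))
    if (!any(diff(gens) == 1L)) return(FALSE)
    dx <- do.call(rbind, lapply(affected[idx], ls_dx))
    if (!any(dx$age < 50)) return(FALSE)
    if (any(tolower(dx$cancer) == "colorectal") && !ped$fap_excluded) {
      return(FALSE)
    }
    # one member first-degree relative of two others in the subset
    any(vapply(idx, function(i) {
      sum(deg[i, setdiff(idx, i)] == 1L) >= 2L
    }, logical(1)))
  }
  n <- length(affected)
  for (k in 3:n) {
    combos <- utils::combn(n, k)
    for (c_i in seq_len(ncol(combos))) {
      if (subset_ok(combos[, c_i])) {
        return(list(met = TRUE, reasons = character()))
      }
    }
  }
  # enumerate which clauses fail over the whole affected set, for the reader
  reasons <- character()
  gens <- sort(unique(vapply(affected, function(m) m$generation, integer(1))))
  if (!any(diff(gens) == 1L)) {
    reasons <- c(reasons, "affected relatives do not span two successive generations")
  }
  all_dx <- do.call(rbind, lapply(affected, ls_dx))
  if (!any(all_dx$age < 50)) {
    reasons <- c(reasons, "no diagnosis before age 50")
  }
  if (!any(vapply(seq_len(n), function(i) {
    sum(deg[i, -i] == 1L) >= 2L
  }, logical(1)))) {
    reasons <- c(reasons, "no affected relative is a first-degree relative of two other affected relatives")
  }
  if (any(tolower(all_dx$cancer) == "colorectal") && !ped$fap_excluded) {
    reasons <- c(reasons, "familial adenomatous polyposis not excluded despite colorectal cancer")
  }
  if (!length(reasons)) {
    reasons <- "no affected subset satisfies all Amsterdam II clauses jointly"
  }
  list(met = FALSE, reasons = reasons)
}

#' Case-level clinical-criteria disjunction
#'
#' Clinical criteria are met when the PREMM5 score reaches the threshold OR
#' the Amsterdam II flag is `"TRUE"` (a disjunction; `"UNKNOWN"` counts as
#' not met).
#'
#' @param clinical A [clinical_evidence()].
#' @param threshold PREMM5 threshold in percent.
#' @return Logical.
#' @export
clinical_criteria_met <- function(clinical, threshold = 2.5) {
  premm5_meets_threshold(clinical$premm5_percent, threshold) ||
    identical(clinical$amsterdam_ii_met, "TRUE")
}

#' Read a pedigree from a tab-delimited file
#'
#' Columns: `id`, `mother_id`, `father_id`, `generation`, `diagnoses`
#' (semicolon-separated `cancer@age` pairs). Header comment lines carry the
#' flags: `# proband: <id>` and `# fap_excluded: TRUE|FALSE`.
#'
#' @param path File path.
#' @return A [pedigree()].
#' @export
read_pedigree <- function(path) {
  lines <- readLines(path)
  header <- grep("^#", lines, value = TRUE)
  get_flag <- function(key, default = NA_character_) {
    hit <- grep(paste0("^#\\s*", key, "\\s*:"), header, value = TRUE)
    if (!length(hit)) return(default)
    trimws(sub(paste0("^#\\s*", key, "\\s*:"), "", hit[1]))
  }
  df <- utils::read.delim(text = lines[!grepl("^#", lines)], sep = "\t",
                          colClasses = "character")
  members <- lapply(seq_len(nrow(df)), function(i) {
    dx_str <- df$diagnoses[i]
    dx <- if (!is.na(dx_str) && nzchar(dx_str)) {
      parts <- strsplit(dx_str, ";", fixed = TRUE)[[1]]
      do.call(rbind, lapply(parts, function(p) {
        kv <- strsplit(p, "@", fixed = TRUE)[[1]]
        data.frame(cancer = trimws(kv[1]), age = as.numeric(kv[2]))
      }))
    } else NULL
    relative(df$id[i],
             mother_id = ifelse(nzchar(df$mother_id[i]), df$mother_id[i], NA),
             father_id = ifelse(nzchar(df$father_id[i]), df$father_id[i], NA),
             generation = as.integer(df$generation[i]),
             diagnoses = dx)
  })
  pedigree(proband_id = get_flag("proband", df$id[1]),
           members = members,
           fap_excluded = identical(toupper(get_flag("fap_excluded", "FALSE")),
                                    "TRUE"))
}
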