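# Cohort metadata: barcode parsing, institution alias normalization, and
# contribution-group stratification.

#' Parse TCGA-style slide barcodes
#'
#' A slide barcode has the form `TCGA-<TSS>-<participant>[-...]`, where the
#' two-character tissue source site (TSS) code identifies the contributing
#' institution (and project). The patient identity is the first three
#' fields joined.
#'
#' @param slide_id character vector of barcode-style identifiers.
#' @return A data.frame with columns `slide_id`, `site_code` (2 characters)
#'   and `patient_id`.
#' @examples
#' parse_barcode("TCGA-02-0001-01Z")
#' @export
parse_barcode <- function(slide_id) {
  stopifnot(is.character(slide_id), length(slide_id) >= 1)
  pat <- "^TCGA-([A-Za-z0-9]{2})-([A-Za-z0-9]+)(-.*)?$"
  ok <- grepl(pat, slide_id)
  if (!all(ok))
    stop("malformed slide id(s): ",
         paste(utils::head(slide_id[!ok], 5), collapse = ", "))
  site_code <- sub(pat, "\\1", slide_id)
  participant <- sub(pat, "\\2", slide_id)
  data.frame(slide_id = slide_id,
             site_code = site_code,
             patient_id = paste("TCGA", site_code, participant, sep = "-"),
             stringsAsFactors = FALSE)
}

#' Read an institution alias table
#'
#' The alias table is a two-column TSV (`alias`, `canonical`) mapping
#' inconsistent institution spellings to one canonical name. The table
#' shipped with the package covers known aliases (e.g. MSKCC); it is
#' deliberately editable rather than fuzzy-matched — residual naming
#' ambiguity in public cohorts is a documented data defect, and silently
#' guessing would hide it.
#'
#' @param path TSV path; defaults to the packaged table.
#' @return data.frame with columns `alias`, `canonical`.
#' @export
read_alias_table <- function(path = system.file("extdata",
                                                "institution_aliases.tsv",
                                                package = "sitebias")) {
  tab <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  stopifnot(all(c("alias", "canonical") %in% names(tab)))
  tab
}

#' Normalize institution names through an alias table
#'
#' Known aliases are replaced by their canonical name; unknown names pass
#' through unchanged (optionally with a warning listing them once). No
#' fuzzy matching is attempted.
#'
#' @param raw_name character vector of institution names.
#' @param alias_table data.frame with columns `alias`, `canonical` (default
#'   the packaged table; an empty table makes this the identity).
#' @param warn emit one warning listing names not found in the table
#'   (default `FALSE`).
#' @return character vector of canonical names.
#' @examples
#' normalize_institution("MSKCC")
#' @export
normalize_institution <- function(raw_name,
                                  alias_table = read_alias_table(),
                                  warn = FALSE) {
  stopifnot(is.character(raw_name))
  idx <- match(raw_name, alias_table$alias)
  out <- ifelse(is.na(idx), raw_name, alias_table$canonical[idx])
  if (warn && anyNA(idx)) {
    unknown <- unique(raw_name[is.na(idx)])
    warning("institution name(s) not in alias table, passed through: ",
            paste(utils::head(unknown, 10), collapse = "; "))
  }
  out
}

#' Stratify acquisition sites into contribution groups A and B
#'
#' Group A holds the institutions contributing strictly more than
#' `threshold` of all slides; group B the rest. Analyzing the two groups
#' separately keeps high-volume institutions from skewing per-site
#' classification metrics. Grouping is by (normalized) institution name,
#' since one institution may own several TSS codes across projects. The
#' boundary is strict: a site at exactly the threshold falls in B.
#'
#' @param records manifest data.frame with an `institution` column (one row
#'   per slide).
#' @param threshold contribution fraction (default 0.01).
#' @return A data.frame of class `group_assignment` with columns
#'   `institution`, `n_slides`, `share`, `group`, ordered by decreasing
#'   share; the threshold is stored as an attribute.
#' @examples
#' m <- data.frame(institution = rep(c("A", "B"), c(98, 2)))
#' assign_groups(m, threshold = 0.01)
#' @export
assign_groups <- function(records, threshold = 0.01) {
  stopifnot(is.data.frame(records), nrow(records) > 0,
            "institution" %in% names(records),
            threshold >= 0, threshold < 1)
  tab <- table(records$institution)
  share <- as.numeric(tab) / nrow(records)
  out <- data.frame(institution = names(tab),
                    n_slides = as.integer(tab),
                    share = share,
                    group = ifelse(share > threshold, "A", "B"),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$share, out$institution), ]
  rownames(out) <- NULL
  attr(out, "threshold") <- threshold
  class(out) <- c("group_assignment", "data.frame")
  out
}

#' Institutions in a contribution group
#'
#' @param groups a [assign_groups()] result.
#' @param group `"A"` or `"B"`.
#' @return character vector of institution names.
#' @export
group_members <- function(groups, group = c("A", "B")) {
  group <- match.arg(group)
  groups$institution[groups$group == group]
}
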