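# On-disk interchange: TSV manifests, a per-slide feature store with a TSV
# index, optional PNG patch stores, and audit outputs.

#' Write / read a slide manifest
#'
#' The manifest is a TSV with one row per slide and columns `slide_id`,
#' `patient_id`, `site_code`, `institution`, `project` (extra columns are
#' preserved).
#'
#' @param manifest data.frame.
#' @param path TSV path.
#' @return `read_manifest` returns the data.frame; `write_manifest`
#'   returns `path` invisibly.
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(all(c("slide_id", "patient_id", "site_code", "institution",
                  "project") %in% names(manifest)))
  write.table(manifest, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  m <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                  colClasses = "character")
  stopifnot(all(c("slide_id", "patient_id", "site_code", "institution",
                  "project") %in% names(m)))
  if ("class_id" %in% names(m)) m$class_id <- as.integer(m$class_id)
  if ("site_index" %in% names(m)) m$site_index <- as.integer(m$site_index)
  m
}

#' Write / read a feature store
#'
#' One serialized matrix per slide (`<slide_id>.rds`) plus a TSV index
#' (`index.tsv`: `slide_id`, `n_patches`, `d`, `extractor`) and the
#' manifest. Reading reconstructs a feature-mode `site_cohort`.
#'
#' @param cohort feature-mode `site_cohort`.
#' @param dir output directory (created if missing).
#' @return `write_feature_store` returns `dir` invisibly;
#'   `read_feature_store` returns a `site_cohort`.
#' @export
write_feature_store <- function(cohort, dir) {
  stopifnot(inherits(cohort, "site_cohort"), cohort$mode == "features")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  extractor <- cohort$extractor %||% "synthetic"
  idx <- data.frame(slide_id = names(cohort$features),
                    n_patches = vapply(cohort$features, nrow, integer(1)),
                    d = vapply(cohort$features, ncol, integer(1)),
                    extractor = extractor, stringsAsFactors = FALSE)
  for (id in names(cohort$features))
    saveRDS(cohort$features[[id]], file.path(dir, paste0(id, ".rds")))
  write.table(idx, file.path(dir, "index.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_manifest(cohort$manifest, file.path(dir, "manifest.tsv"))
  invisible(dir)
}

#' @rdname write_feature_store
#' @export
read_feature_store <- function(dir) {
  idx <- read.delim(file.path(dir, "index.tsv"), sep = "\t",
                    stringsAsFactors = FALSE)
  manifest <- read_manifest(file.path(dir, "manifest.tsv"))
  feats <- lapply(idx$slide_id, function(id)
    readRDS(file.path(dir, paste0(id, ".rds"))))
  names(feats) <- idx$slide_id
  structure(list(manifest = manifest, features = feats, config = NULL,
                 mode = "features", extractor = idx$extractor[1]),
            class = "site_cohort")
}

#' Write an image-mode cohort as a PNG patch store
#'
#' Patches are written as `<slide_id>_<patch_index>.png` with a TSV patch
#' index (`slide_id`, `patch_index`, `x`, `y`, `level`, `file`). Requires
#' the png package.
#'
#' @param cohort image-mode `site_cohort`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_patch_store <- function(cohort, dir) {
  stopifnot(inherits(cohort, "site_cohort"), cohort$mode == "images")
  if (!requireNamespace("png", quietly = TRUE))
    stop("write_patch_store requires the png package")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  idx <- list()
  for (id in names(cohort$slides)) {
    slide <- cohort$slides[[id]]
    for (j in seq_along(slide$patches)) {
      file <- paste0(id, "_", j - 1L, ".png")
      png::writePNG(slide$patches[[j]], file.path(dir, file))
      idx[[length(idx) + 1L]] <- data.frame(
        slide_id = id, patch_index = j - 1L,
        x = slide$coords$x[j], y = slide$coords$y[j],
        level = slide$coords$level[j], file = file,
        stringsAsFactors = FALSE)
    }
  }
  write.table(do.call(rbind, idx), file.path(dir, "patches.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_manifest(cohort$manifest, file.path(dir, "manifest.tsv"))
  invisible(dir)
}

#' Write a bias audit to TSV and JSON
#'
#' @param report a [audit_report()].
#' @param dir output directory; writes `audit.tsv` and `audit.json`.
#' @return `dir`, invisibly.
#' @export
write_audit <- function(report, dir) {
  stopifnot(inherits(report, "bias_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  df <- as.data.frame(report)
  write.table(df, file.path(dir, "audit.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  payload <- list(k = attr(report, "k"), metric = attr(report, "metric"),
                  n_perm = attr(report, "n_perm"),
                  seed = attr(report, "seed"), table = df)
  jsonlite::write_json(payload, file.path(dir, "audit.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}
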