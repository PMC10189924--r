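# Patch feature extraction behind a pluggable contract.
#
# An extractor is any function (raster, context) -> numeric vector of a
# fixed width, deterministic for fixed parameters. The handcrafted
# baseline below needs no trained weights; adapters to pretrained CNNs can
# be dropped in without touching the rest of the pipeline.

# version tag of the shipped projection constant
.PROJ_VERSION <- "v1"
.PROJ_SEED <- 770424L

proj_cache <- new.env(parent = emptyenv())

# Fixed random projection matrix (d x m), regenerated bit-identically from
# a shipped seed constant and cached per (d, m, stream).
projection_matrix <- function(d, m, stream = 0L) {
  key <- paste(d, m, stream, sep = "_")
  if (is.null(proj_cache[[key]])) {
    proj_cache[[key]] <- with_seed(derive_seed(.PROJ_SEED, stream),
                                   matrix(rnorm(d * m) / sqrt(m), d, m))
  }
  proj_cache[[key]]
}

# Raw descriptor blocks for one raster:
#   * per-channel histograms (16 bins x 3, each block L1-normalized);
#   * gradient-orientation histogram of luminance (8 bins, magnitude
#     weighted, L1-normalized; all-zero on constant patches);
#   * local-variance pyramid (per-channel variance at block-mean
#     downsampling factors 1, 2, 4, 8).
baseline_blocks <- function(patch) {
  stopifnot(length(dim(patch)) == 3, dim(patch)[3] == 3)
  histo <- as.numeric(rgb_histograms(list(patch), bins = 16))
  lum <- (patch[, , 1] + patch[, , 2] + patch[, , 3]) / 3
  h <- nrow(lum); w <- ncol(lum)
  gx <- lum[, c(2:w, w)] - lum
  gy <- lum[c(2:h, h), ] - lum
  mag <- sqrt(gx^2 + gy^2)
  grad <- numeric(8)
  if (sum(mag) > 0) {
    ang <- atan2(gy, gx)                       # (-pi, pi]
    bin <- pmin(floor((ang + pi) / (2 * pi) * 8) + 1L, 8L)
    grad <- vapply(1:8, function(b) sum(mag[bin == b]), numeric(1))
    grad <- grad / sum(grad)
  }
  pyr <- unlist(lapply(c(1L, 2L, 4L, 8L), function(f) {
    vapply(1:3, function(ch) {
      v <- block_mean(patch[, , ch], f)
      if (length(v) > 1) stats::var(as.numeric(v)) else 0
    }, numeric(1))
  }))
  c(histo, grad, pyr)
}

block_mean <- function(m, f) {
  if (f == 1L) return(m)
  h <- (nrow(m) %/% f) * f; w <- (ncol(m) %/% f) * f
  m <- m[seq_len(h), seq_len(w), drop = FALSE]
  rowsum_idx <- rep(seq_len(h %/% f), each = f)
  colsum_idx <- rep(seq_len(w %/% f), each = f)
  t(rowsum(t(rowsum(m, rowsum_idx)), colsum_idx)) / (f * f)
}

#' Deterministic handcrafted patch feature extractor
#'
#' Concatenates per-channel color histograms, a gradient-orientation
#' histogram, and a local-variance pyramid (68 raw descriptors), then maps
#' them through a fixed seeded random projection to `d` dimensions. The
#' projection matrix is regenerated bit-identically from a shipped seed
#' constant (version `"v1"`), so features are reproducible across sessions
#' with no trained weights.
#'
#' @param patch `h x w x 3` array in \[0, 1\].
#' @param context ignored (present to satisfy the extractor contract).
#' @param d output width (default 1024).
#' @return numeric vector of length `d`.
#' @export
baseline_extractor <- function(patch, context = NULL, d = 1024) {
  raw <- baseline_blocks(patch)
  as.numeric(projection_matrix(d, length(raw), stream = 0L) %*% raw)
}

#' Site-aware oracle extractor
#'
#' The baseline descriptors augmented with an oracle block: the site's true
#' stain-matrix deviation (9 entries) and noise amplitude, read from the
#' generation context. This gives an upper-bound "extractor that has
#' learned the site cues", used to demonstrate that a site-informed
#' representation carries strictly more acquisition-site signal than the
#' plain baseline. It requires generator ground truth and is meaningless on
#' real data.
#'
#' @param patch `h x w x 3` array in \[0, 1\].
#' @param context list with a `site_effect` element (supplied by
#'   [extract_cohort_features()]).
#' @param d output width (default 1024).
#' @param oracle_gain multiplier bringing the small stain-deviation entries
#'   to the scale of the image descriptors (default 25). At zero site
#'   effect the oracle block is exactly zero regardless of gain.
#' @return numeric vector of length `d`.
#' @export
site_aware_extractor <- function(patch, context, d = 1024, oracle_gain = 25) {
  if (is.null(context$site_effect))
    stop("site_aware_extractor needs the generating site_effect in `context`")
  eff <- context$site_effect
  raw <- c(baseline_blocks(patch),
           oracle_gain * as.numeric(eff$stain_matrix - diag(3)),
           oracle_gain * eff$noise_amplitude)
  as.numeric(projection_matrix(d, length(raw), stream = 1L) %*% raw)
}

#' Extract per-patch features for one slide
#'
#' Applies an extractor to every patch of a [sample_mosaic()] patch set (or
#' any list of rasters), preserving patch order. The extractor must return
#' a constant-width finite numeric vector; violations are hard errors.
#'
#' @param patch_set a `patch_set`, or a list of rasters.
#' @param extractor extractor function `(raster, context) -> numeric(d)`
#'   (default [baseline_extractor()]).
#' @param context optional list passed to the extractor.
#' @param extractor_name tag recorded in the result.
#' @return Object of class `slide_features`: `slide_id`, matrix `x`
#'   (`n_patches x d`), `extractor`.
#' @export
extract_features <- function(patch_set, extractor = baseline_extractor,
                             context = NULL,
                             extractor_name = deparse(substitute(extractor))) {
  if (is.list(patch_set) && !is.null(patch_set$patches)) {
    patches <- patch_set$patches
    slide_id <- patch_set$slide_id %||% NA_character_
  } else {
    patches <- patch_set
    slide_id <- NA_character_
  }
  if (length(patches) == 0) stop("empty patch set: nothing to extract")
  rows <- lapply(patches, function(p) {
    v <- extractor(p, context)
    if (!is.numeric(v)) stop("extractor returned a non-numeric value")
    if (any(!is.finite(v))) stop("extractor returned non-finite values")
    v
  })
  widths <- lengths(rows)
  if (length(unique(widths)) != 1)
    stop("extractor returned inconsistent widths: ",
         paste(unique(widths), collapse = ", "))
  structure(list(slide_id = slide_id,
                 x = do.call(rbind, rows),
                 extractor = extractor_name),
            class = "slide_features")
}

#' Extract features for every slide of an image-mode cohort
#'
#' Runs [sample_mosaic()] (optional) and [extract_features()] over all
#' slides, passing each slide's generating `site_effect` as extractor
#' context, and returns a feature-mode `site_cohort` so downstream stages
#' (probe, search, audit) are agnostic to how features were produced.
#'
#' @param cohort an image-mode `site_cohort`.
#' @param extractor extractor function (default [baseline_extractor()]).
#' @param mosaic optional [mosaic_config()]; `NULL` (default) uses every
#'   patch of every slide.
#' @param extractor_name tag recorded in the result.
#' @return A feature-mode `site_cohort`.
#' @export
extract_cohort_features <- function(cohort, extractor = baseline_extractor,
                                    mosaic = NULL,
                                    extractor_name = deparse(substitute(extractor))) {
  stopifnot(inherits(cohort, "site_cohort"), cohort$mode == "images")
  feats <- lapply(seq_len(nrow(cohort$manifest)), function(i) {
    slide <- cohort$slides[[cohort$manifest$slide_id[i]]]
    if (!is.null(mosaic)) slide <- sample_mosaic(slide, mosaic)
    ctx <- list(site_effect = cohort$site_effects[[cohort$manifest$site_index[i]]])
    extract_features(slide, extractor, context = ctx,
                     extractor_name = extractor_name)$x
  })
  names(feats) <- cohort$manifest$slide_id
  structure(list(manifest = cohort$manifest, features = feats,
                 config = cohort$config, mode = "features",
                 extractor = extractor_name),
            class = "site_cohort")
}

#' Pool a slide's patch features into one vector
#'
#' @param sf a `slide_features`, or a numeric matrix (rows = patches).
#' @param method pooling method; only `"mean"` (column-wise mean) is
#'   defined.
#' @return numeric vector of length `d`.
#' @export
pool_features <- function(sf, method = c("mean")) {
  method <- match.arg(method)
  x <- as_feature_matrix(sf)
  if (nrow(x) == 0) stop("cannot pool an empty feature matrix")
  colMeans(x)
}

#' Z-score a feature cohort
#'
#' Standardizes every feature dimension to zero mean and unit variance
#' across all patches of the cohort. Off the default path: raw embeddings
#' are conventionally consumed unnormalized, but a standardized variant is
#' useful for sensitivity checks. Constant dimensions are left centered.
#'
#' @param cohort feature-mode `site_cohort`.
#' @return the cohort with standardized feature matrices.
#' @export
zscore_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "site_cohort"), cohort$mode == "features")
  x <- do.call(rbind, cohort$features)
  mu <- colMeans(x)
  sdv <- apply(x, 2, sd)
  sdv[sdv == 0] <- 1
  cohort$features <- lapply(cohort$features, function(f)
    sweep(sweep(f, 2, mu), 2, sdv, "/"))
  cohort
}

as_feature_matrix <- function(x) {
  if (inherits(x, "slide_features")) x <- x$x
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  stopifnot(is.numeric(x))
  x
}
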