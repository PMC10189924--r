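#' Configuration for a synthetic multi-site slide cohort
#'
#' Describes a cohort of whole-slide images contributed by several
#' acquisition sites (hospitals), each with its own stain transform and
#' noise texture, and several cancer-type classes with site-dependent
#' composition. A single knob, `site_effect_alpha`, scales both site-effect
#' mechanisms; at `alpha = 0` all sites draw from identical distributions.
#'
#' @param n_sites number of acquisition sites.
#' @param n_slides total number of slides in the cohort.
#' @param n_classes number of cancer-type classes (projects).
#' @param site_shares per-site fraction of slides; must sum to 1. Default
#'   equal shares.
#' @param class_given_site `n_sites x n_classes` matrix of class
#'   probabilities per site; each row must sum to 1. Degenerate one-class
#'   rows are allowed (a site contributing a single cancer type). Default
#'   uniform.
#' @param patches_per_slide patches sampled per slide (default 55, the
#'   typical mosaic size for a whole-slide image).
#' @param patch_px patch edge length in pixels for image mode (default 128,
#'   a desk-scale stand-in for 1000 x 1000 patches; configurable up to 1000).
#' @param multi_slide_patient_frac fraction of patients owning two slides
#'   (default 0.07, mirroring the minority of multi-slide patients in large
#'   public cohorts).
#' @param site_effect_alpha nonnegative scalar scaling both the per-site
#'   stain-matrix deviation and the per-site noise amplitude. 0 switches the
#'   site effect off entirely.
#' @param feature_dim feature width for feature mode (default 1024, the
#'   width of a typical last-pooling-layer embedding).
#' @param class_sep expected norm of a class mean vector in feature space
#'   (default 6; noise is unit isotropic, so classes are well separated).
#' @param site_shift_scale norm of the per-site shift vector in feature
#'   space at `alpha = 1` (default 2).
#' @param seed integer seed; every generator output is a pure function of
#'   the full configuration including this seed.
#' @return An object of class `cohort_config` (a validated list).
#' @seealso [generate_cohort()], [generate_feature_cohort()]
#' @examples
#' cfg <- cohort_config(n_sites = 4, n_slides = 40, seed = 1)
#' @export
cohort_config <- function(n_sites,
                          n_slides,
                          n_classes = 3,
                          site_shares = NULL,
                          class_given_site = NULL,
                          patches_per_slide = 55,
                          patch_px = 128,
                          multi_slide_patient_frac = 0.07,
                          site_effect_alpha = 1,
                          feature_dim = 1024,
                          class_sep = 6,
                          site_shift_scale = 2,
                          seed = 1) {
  stopifnot(n_sites >= 1, n_slides >= 1, n_classes >= 1,
            patches_per_slide >= 1, patch_px >= 32,
            multi_slide_patient_frac >= 0, multi_slide_patient_frac < 1,
            site_effect_alpha >= 0, feature_dim >= 2,
            class_sep >= 0, site_shift_scale >= 0)
  if (is.null(site_shares)) site_shares <- rep(1 / n_sites, n_sites)
  if (length(site_shares) != n_sites)
    stop("`site_shares` must have length `n_sites` (", n_sites, "), got ",
         length(site_shares))
  if (abs(sum(site_shares) - 1) > 1e-9)
    stop("`site_shares` must sum to 1 (got ", format(sum(site_shares)), ")")
  if (is.null(class_given_site))
    class_given_site <- matrix(1 / n_classes, n_sites, n_classes)
  class_given_site <- as.matrix(class_given_site)
  if (!all(dim(class_given_site) == c(n_sites, n_classes)))
    stop("`class_given_site` must be an n_sites x n_classes matrix")
  if (any(abs(rowSums(class_given_site) - 1) > 1e-9))
    stop("each row of `class_given_site` must sum to 1")
  if (any(class_given_site < 0))
    stop("`class_given_site` entries must be nonnegative")

  structure(list(
    n_sites = as.integer(n_sites),
    n_slides = as.integer(n_slides),
    n_classes = as.integer(n_classes),
    site_shares = as.numeric(site_shares),
    class_given_site = class_given_site,
    patches_per_slide = as.integer(patches_per_slide),
    patch_px = as.integer(patch_px),
    multi_slide_patient_frac = multi_slide_patient_frac,
    site_effect_alpha = site_effect_alpha,
    feature_dim = as.integer(feature_dim),
    class_sep = class_sep,
    site_shift_scale = site_shift_scale,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config> ", x$n_slides, " slides, ", x$n_sites, " sites, ",
      x$n_classes, " classes; alpha = ", x$site_effect_alpha,
      "; seed = ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Per-site image-domain effects
#'
#' Draws, once per cohort, each site's stain transform and noise texture.
#' The stain transform is `I + alpha * Delta` with `Delta` entries uniform
#' in \[-0.15, 0.15\] (a near-identity color-mixing matrix emulating
#' site-specific H&E stain spectra); the noise texture is a fixed
#' band-limited Gaussian field keyed by a per-site seed, with amplitude
#' `alpha * 0.05` of the dynamic range (emulating scanner noise). At
#' `alpha = 0` the transform is exactly the identity and the amplitude 0.
#'
#' The underlying `Delta` and texture seeds depend only on `config$seed`
#' and the site index, never on `alpha`, so varying `alpha` moves the same
#' site effects along a common path.
#'
#' @param config a [cohort_config()].
#' @return A list (one element per site) of `site_effect` objects with
#'   fields `stain_matrix`, `noise_texture_seed`, `noise_amplitude`.
#' @export
site_effects <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  alpha <- config$site_effect_alpha
  with_seed(derive_seed(config$seed, 101), {
    lapply(seq_len(config$n_sites), function(s) {
      delta <- matrix(runif(9, -0.15, 0.15), 3, 3)
      structure(list(
        stain_matrix = diag(3) + alpha * delta,
        noise_texture_seed = derive_seed(config$seed, 5000 + s),
        noise_amplitude = alpha * 0.05
      ), class = "site_effect")
    })
  })
}
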