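# Synthetic multi-site cohort generator.
#
# Two generation modes share one manifest builder:
#   * image mode   - renders RGB patch rasters with class-dependent nuclei
#                    morphology plus per-site stain/noise effects;
#   * feature mode - draws per-patch feature vectors directly
#                    (class mean + alpha * site shift + unit noise),
#                    bypassing rendering for fast probe/search experiments.

build_manifest <- function(config) {
  counts <- largest_remainder(config$site_shares, config$n_slides)
  f <- config$multi_slide_patient_frac
  rows <- vector("list", config$n_sites)
  patient_counter <- 0L
  for (s in seq_len(config$n_sites)) {
    m <- counts[s]
    if (m == 0L) next
    # t two-slide patients and (m - 2t) singles so that t / n_patients ~ f
    t2 <- min(m %/% 2L, round(m * f / (1 + f)))
    n_pat <- (m - 2L * t2) + t2
    slides_per_patient <- c(rep(2L, t2), rep(1L, n_pat - t2))
    code <- site_code_for(s)
    cls <- apply(stats::rmultinom(n_pat, 1L, config$class_given_site[s, ]),
                 2, which.max)
    site_rows <- vector("list", n_pat)
    for (p in seq_len(n_pat)) {
      patient_counter <- patient_counter + 1L
      pid <- sprintf("TCGA-%s-%04d", code, patient_counter)
      k <- slides_per_patient[p]
      site_rows[[p]] <- data.frame(
        slide_id = sprintf("%s-DX%d", pid, seq_len(k)),
        patient_id = pid,
        site_code = code,
        institution = paste0("Hospital ", code),
        project = sprintf("PR%02d", cls[p]),
        class_id = cls[p],
        site_index = s,
        stringsAsFactors = FALSE
      )
    }
    rows[[s]] <- do.call(rbind, site_rows)
  }
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  manifest
}

#' Generate a synthetic multi-site cohort
#'
#' Builds a slide manifest honoring the configured site shares
#' (largest-remainder apportionment, so each site's slide count differs
#' from `share * n_slides` by less than one) and the multi-slide-patient
#' fraction, then populates each slide with either rendered RGB patches or
#' feature vectors. All output is a pure function of `config`, including
#' its seed.
#'
#' @param config a [cohort_config()].
#' @param mode `"features"` (default) to draw per-patch feature vectors
#'   directly, or `"images"` to render RGB patch rasters.
#' @return An object of class `site_cohort`: a list with `manifest` (one
#'   row per slide: `slide_id`, `patient_id`, `site_code`, `institution`,
#'   `project`), `config`, `mode`, and either `features` (named list of
#'   `n_patches x feature_dim` matrices) or `slides` (named list of slide
#'   objects with `patches` rasters and `coords`) plus `site_effects`.
#'   Feature mode also carries `truth` (class means and site shift
#'   vectors) for oracle checks.
#' @examples
#' cfg <- cohort_config(n_sites = 3, n_slides = 12, patches_per_slide = 5,
#'                      feature_dim = 8, seed = 1)
#' coh <- generate_cohort(cfg)
#' table(coh$manifest$site_code)
#' @export
generate_cohort <- function(config, mode = c("features", "images")) {
  stopifnot(inherits(config, "cohort_config"))
  mode <- match.arg(mode)
  if (mode == "features") return(generate_feature_cohort(config))

  manifest <- with_seed(derive_seed(config$seed, 1), build_manifest(config))
  effects <- site_effects(config)
  px <- config$patch_px
  ncol_grid <- ceiling(sqrt(config$patches_per_slide))
  slides <- with_seed(derive_seed(config$seed, 2), {
    lapply(seq_len(nrow(manifest)), function(i) {
      s <- manifest$site_index[i]
      patches <- lapply(seq_len(config$patches_per_slide), function(j)
        render_patch(manifest$class_id[i], effects[[s]], patch_px = px))
      idx <- seq_len(config$patches_per_slide) - 1L
      list(slide_id = manifest$slide_id[i],
           patches = patches,
           coords = data.frame(x = (idx %% ncol_grid) * px,
                               y = (idx %/% ncol_grid) * px,
                               level = 0L))
    })
  })
  names(slides) <- manifest$slide_id
  structure(list(manifest = manifest, slides = slides,
                 site_effects = effects, config = config, mode = "images"),
            class = "site_cohort")
}

#' Generate a cohort directly in feature space
#'
#' Fast path that skips rendering: each patch feature vector is
#' `class_mean + alpha * site_shift + noise`, with class means and unit
#' site-shift directions drawn once per cohort from the seed, and unit
#' isotropic Gaussian noise. Class means have expected norm `class_sep`;
#' site shifts have norm `alpha * site_shift_scale`. At `alpha = 0` all
#' sites share one distribution per class.
#'
#' @param config a [cohort_config()].
#' @return A `site_cohort` in feature mode (see [generate_cohort()]).
#' @export
generate_feature_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"), config$feature_dim >= 2)
  manifest <- with_seed(derive_seed(config$seed, 1), build_manifest(config))
  d <- config$feature_dim
  alpha <- config$site_effect_alpha
  truth <- with_seed(derive_seed(config$seed, 3), {
    class_means <- matrix(rnorm(config$n_classes * d, sd = config$class_sep / sqrt(d)),
                          config$n_classes, d)
    dirs <- matrix(rnorm(config$n_sites * d), config$n_sites, d)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    list(class_means = class_means,
         site_shifts = config$site_shift_scale * dirs)
  })
  np <- config$patches_per_slide
  features <- with_seed(derive_seed(config$seed, 4), {
    lapply(seq_len(nrow(manifest)), function(i) {
      mu <- truth$class_means[manifest$class_id[i], ] +
        alpha * truth$site_shifts[manifest$site_index[i], ]
      matrix(rnorm(np * d), np, d) + rep(mu, each = np)
    })
  })
  names(features) <- manifest$slide_id
  structure(list(manifest = manifest, features = features,
                 truth = truth, config = config, mode = "features"),
            class = "site_cohort")
}

#' @export
print.site_cohort <- function(x, ...) {
  cat("<site_cohort> ", nrow(x$manifest), " slides, ",
      length(unique(x$manifest$site_code)), " sites, ",
      length(unique(x$manifest$project)), " projects; mode = ", x$mode,
      "\n", sep = "")
  invisible(x)
}

# class-dependent nuclei morphology proxy
class_morphology <- function(class_id) {
  if (class_id == 0) return(list(lambda = 0, radius = 4))
  list(lambda = 40 * (1 + 0.8 * (class_id - 1)),
       radius = 4 * (1 + 0.25 * ((class_id - 1) %% 4)))
}

#' Render one synthetic H&E-like patch
#'
#' Paints elliptical dark "nuclei" on a near-white eosin background; nuclei
#' density and size depend on `class_id` (class 0 is the blank class with
#' zero density). Pixels are then passed through the site's stain-mixing
#' matrix and perturbed by the site's fixed band-limited noise field, and
#' clipped to \[0, 1\]. Rendering consumes the current RNG stream unless
#' `seed` is given.
#'
#' @param class_id integer class (0 allowed: background only).
#' @param site_effect a `site_effect` from [site_effects()].
#' @param patch_px patch edge length in pixels (>= 32).
#' @param seed optional integer; if given, rendering is a pure function of
#'   it.
#' @return `patch_px x patch_px x 3` array in \[0, 1\] with attribute
#'   `nucleus_mask`, the ground-truth logical matrix of painted nucleus
#'   pixels (before stain/noise).
#' @export
render_patch <- function(class_id, site_effect, patch_px = 128, seed = NULL) {
  stopifnot(class_id >= 0, patch_px >= 32,
            inherits(site_effect, "site_effect"))
  if (!is.null(seed)) return(with_seed(seed, render_patch(class_id, site_effect, patch_px)))
  px <- patch_px
  morph <- class_morphology(class_id)
  bg <- c(0.94, 0.91, 0.93)
  raster <- array(rep(bg, each = px * px), dim = c(px, px, 3))
  mask <- matrix(FALSE, px, px)
  lambda <- morph$lambda * (px / 128)^2
  n <- if (lambda > 0) rpois(1, lambda) else 0L
  base_col <- c(0.32, 0.22, 0.52)  # hematoxylin-like dark purple
  if (n > 0) {
    cx <- runif(n, 1, px); cy <- runif(n, 1, px)
    a <- morph$radius * runif(n, 0.7, 1.3)
    b <- morph$radius * runif(n, 0.5, 1.0)
    th <- runif(n, 0, pi)
    jit <- matrix(rnorm(3 * n, 0, 0.03), n, 3)
    for (i in seq_len(n)) {
      r <- ceiling(max(a[i], b[i]))
      xs <- max(1, floor(cx[i] - r)):min(px, ceiling(cx[i] + r))
      ys <- max(1, floor(cy[i] - r)):min(px, ceiling(cy[i] + r))
      dx <- outer(xs - cx[i], rep(1, length(ys)))
      dy <- outer(rep(1, length(xs)), ys - cy[i])
      u <- (dx * cos(th[i]) + dy * sin(th[i])) / a[i]
      v <- (-dx * sin(th[i]) + dy * cos(th[i])) / b[i]
      inside <- (u^2 + v^2) <= 1
      if (!any(inside)) next
      col <- pmin(pmax(base_col + jit[i, ], 0), 1)
      for (ch in 1:3) {
        plane <- raster[, , ch]
        sub <- plane[xs, ys]
        sub[inside] <- col[ch]
        plane[xs, ys] <- sub
        raster[, , ch] <- plane
      }
      msub <- mask[xs, ys]; msub[inside] <- TRUE; mask[xs, ys] <- msub
    }
  }
  flat <- matrix(raster, ncol = 3) %*% t(site_effect$stain_matrix)
  if (site_effect$noise_amplitude > 0) {
    field <- band_limited_noise(px, site_effect$noise_texture_seed)
    flat <- flat + site_effect$noise_amplitude * as.numeric(field)
  }
  out <- array(pmin(pmax(flat, 0), 1), dim = c(px, px, 3))
  attr(out, "nucleus_mask") <- mask
  out
}

#' Band-limited Gaussian noise field
#'
#' A fixed pseudo-random texture: white Gaussian noise low-pass filtered in
#' the Fourier domain (Gaussian transfer function with cutoff in cycles per
#' pixel), then standardized to zero mean and unit variance. The same seed
#' always yields the same field, so a site's noise texture is a stable
#' fingerprint.
#'
#' @param n field edge length in pixels.
#' @param seed integer seed keying the texture.
#' @param cutoff low-pass cutoff frequency in cycles/pixel (default 0.15).
#' @return `n x n` numeric matrix, mean 0, sd 1.
#' @export
band_limited_noise <- function(n, seed, cutoff = 0.15) {
  stopifnot(n >= 2, cutoff > 0)
  white <- with_seed(seed, matrix(rnorm(n * n), n, n))
  fr <- c(seq(0, floor(n / 2)), seq.int(-(ceiling(n / 2) - 1), -1)) / n
  f2 <- outer(fr^2, fr^2, "+")
  mask <- exp(-f2 / cutoff^2)
  field <- Re(fft(fft(white) * mask, inverse = TRUE)) / (n * n)
  (field - mean(field)) / sd(field)
}

#' Histogram-equalize a patch to expose low-amplitude noise
#'
#' Per-channel histogram equalization (continuous empirical-CDF mapping):
#' each channel's values are replaced by their empirical CDF, stretching
#' faint background textures across the full dynamic range. Used as a
#' diagnostic to visualize site-specific noise that is invisible in the raw
#' patch. A constant-valued channel carries no ordering information and is
#' returned unchanged. The mapping is idempotent: ranks are preserved, so a
#' second application returns the same raster.
#'
#' @param patch `h x w x 3` array in \[0, 1\].
#' @return Equalized array of the same shape.
#' @export
amplify_noise <- function(patch) {
  stopifnot(length(dim(patch)) == 3, dim(patch)[3] == 3)
  out <- patch
  for (ch in 1:3) {
    v <- patch[, , ch]
    if (max(v) - min(v) <= 0) next
    out[, , ch] <- matrix(ecdf(v)(v), nrow(v), ncol(v))
  }
  attr(out, "nucleus_mask") <- attr(patch, "nucleus_mask")
  out
}
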