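# Shared small fixtures, built in code and memoised per test run.

fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(fixture_env[[key]])) fixture_env[[key]] <- force(expr)
  fixture_env[[key]]
}

# small feature-mode cohort, strong site effect
strong_cohort <- function() memo("strong", {
  generate_cohort(cohort_config(n_sites = 4, n_slides = 60, n_classes = 2,
                                patches_per_slide = 10, feature_dim = 64,
                                site_effect_alpha = 3, seed = 7))
})

# small feature-mode cohort, no site effect
null_cohort <- function() memo("null", {
  generate_cohort(cohort_config(n_sites = 4, n_slides = 60, n_classes = 2,
                                patches_per_slide = 10, feature_dim = 64,
                                site_effect_alpha = 0, seed = 7))
})

# small image-mode cohort
image_cohort <- function() memo("image", {
  generate_cohort(cohort_config(n_sites = 3, n_slides = 9, n_classes = 2,
                                patches_per_slide = 8, patch_px = 64,
                                site_effect_alpha = 1, seed = 5),
                  mode = "images")
})

a_site_effect <- function(alpha = 1, seed = 1) {
  cfg <- cohort_config(n_sites = 2, n_slides = 2, site_effect_alpha = alpha,
                       seed = seed)
  site_effects(cfg)
}

# brute-force double-loop oracle for the median-of-min slide distance
brute_median_of_min <- function(a, b, median_type = "lower") {
  mins <- numeric(nrow(a))
  for (i in seq_len(nrow(a))) {
    best <- Inf
    for (j in seq_len(nrow(b))) {
      d <- sqrt(sum((a[i, ] - b[j, ])^2))
      if (d < best) best <- d
    }
    mins[i] <- best
  }
  v <- sort(mins)
  n <- length(v)
  if (median_type == "midpoint" && n %% 2 == 0)
    return((v[n / 2] + v[n / 2 + 1]) / 2)
  v[(n + 1) %/% 2]
}
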