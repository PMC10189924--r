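test_that("cohort_config validates its invariants", {
  expect_error(cohort_config(n_sites = 3, n_slides = 10,
                             site_shares = c(0.5, 0.4)),
               "length")
  expect_error(cohort_config(n_sites = 2, n_slides = 10,
                             site_shares = c(0.6, 0.5)),
               "sum to 1")
  expect_error(cohort_config(n_sites = 2, n_slides = 10, n_classes = 2,
                             class_given_site = matrix(c(0.9, 0.3, 0.2, 0.6),
                                                       2, 2)),
               "sum to 1")
  expect_s3_class(cohort_config(n_sites = 2, n_slides = 10), "cohort_config")
})

test_that("per-site slide counts follow the configured shares", {
  cfg <- cohort_config(n_sites = 4, n_slides = 40, seed = 3)
  coh <- generate_cohort(cfg)
  expect_equal(unname(as.integer(table(coh$manifest$site_code))),
               rep(10L, 4))

  # one site owning a 20% share of 100 slides gets exactly 20 slides
  cfg2 <- cohort_config(n_sites = 5, n_slides = 100,
                        site_shares = c(0.2, 0.35, 0.25, 0.15, 0.05),
                        seed = 3)
  coh2 <- generate_cohort(cfg2)
  expect_equal(sum(coh2$manifest$site_code == "00"), 20L)
  expect_equal(nrow(coh2$manifest), 100L)
})

test_that("largest-remainder apportionment conserves totals", {
  set.seed(11)
  for (i in 1:50) {
    k <- sample(2:8, 1)
    shares <- runif(k); shares <- shares / sum(shares)
    n <- sample(10:500, 1)
    counts <- largest_remainder(shares, n)
    expect_equal(sum(counts), n)
    expect_true(all(abs(counts - shares * n) < 1))
  }
})

test_that("generation is a pure function of the config seed", {
  cfg <- cohort_config(n_sites = 3, n_slides = 20, patches_per_slide = 4,
                       feature_dim = 16, seed = 42)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$manifest, b$manifest)
  expect_identical(a$features, b$features)
  cfg2 <- cohort_config(n_sites = 3, n_slides = 20, patches_per_slide = 4,
                        feature_dim = 16, seed = 43)
  expect_false(identical(generate_cohort(cfg2)$features, a$features))
})

test_that("multi-slide patients occur at the configured fraction", {
  cfg <- cohort_config(n_sites = 4, n_slides = 400, patches_per_slide = 2,
                       feature_dim = 4, multi_slide_patient_frac = 0.07,
                       seed = 9)
  m <- generate_cohort(cfg)$manifest
  per_patient <- table(m$patient_id)
  frac <- mean(per_patient > 1)
  expect_gt(frac, 0.04)
  expect_lt(frac, 0.10)
  # slides of one patient share site and project
  for (p in names(per_patient[per_patient > 1])) {
    rows <- m[m$patient_id == p, ]
    expect_equal(length(unique(rows$institution)), 1L)
    expect_equal(length(unique(rows$project)), 1L)
  }
})

test_that("feature mode: zero alpha removes all site structure", {
  cfg <- cohort_config(n_sites = 2, n_slides = 40, n_classes = 1,
                       patches_per_slide = 20, feature_dim = 32,
                       site_effect_alpha = 0, seed = 13)
  coh <- generate_cohort(cfg)
  x <- do.call(rbind, coh$features)
  site <- rep(coh$manifest$site_index, each = 20)
  gap <- colMeans(x[site == 1, ]) - colMeans(x[site == 2, ])
  # per-dimension sampling error ~ 1/sqrt(400); the gap norm must match it
  expect_lt(sqrt(sum(gap^2)), 3 * sqrt(ncol(x) / 400))
})

test_that("feature mode: strong site shifts are recoverable by nearest centroid", {
  cfg <- cohort_config(n_sites = 4, n_slides = 50, n_classes = 1,
                       patches_per_slide = 20, feature_dim = 64,
                       site_effect_alpha = 5, seed = 17)
  coh <- generate_cohort(cfg)  # 1,000 patches
  x <- do.call(rbind, coh$features)
  site <- rep(coh$manifest$site_index,
              each = cfg$patches_per_slide)
  centroids <- t(sapply(1:4, function(s) colMeans(x[site == s, ])))
  d2 <- outer(rowSums(x^2), rowSums(centroids^2), "+") -
    2 * tcrossprod(x, centroids)
  assigned <- max.col(-d2)
  expect_gte(mean(assigned == site), 0.99)
})

test_that("rendered patches are identical across sites when alpha is zero", {
  eff <- a_site_effect(alpha = 0, seed = 2)
  expect_equal(eff[[1]]$stain_matrix, diag(3))
  expect_equal(eff[[1]]$noise_amplitude, 0)
  p1 <- render_patch(1, eff[[1]], patch_px = 48, seed = 5)
  p2 <- render_patch(1, eff[[2]], patch_px = 48, seed = 5)
  expect_identical(p1, p2)
})

test_that("stain matrices shift per-pixel mean color as applied", {
  # hand-built near-identity matrices that only darken, so no pixel clips
  # and the mean-color response is exactly linear in the stain matrix
  mk_eff <- function(delta) structure(
    list(stain_matrix = diag(3) + delta, noise_texture_seed = 1L,
         noise_amplitude = 0), class = "site_effect")
  d1 <- matrix(c(-0.05, 0, -0.02, 0, -0.08, 0, -0.03, 0, -0.01), 3, 3)
  d2 <- matrix(c(-0.01, -0.04, 0, -0.06, 0, -0.02, 0, -0.07, -0.03), 3, 3)
  e1 <- mk_eff(d1); e2 <- mk_eff(d2); e0 <- mk_eff(matrix(0, 3, 3))
  n <- 100
  mean_col <- function(e) {
    rowMeans(vapply(seq_len(n), function(i) {
      p <- render_patch(1, e, patch_px = 48, seed = 100 + i)
      c(mean(p[, , 1]), mean(p[, , 2]), mean(p[, , 3]))
    }, numeric(3)))
  }
  m1 <- mean_col(e1)
  m2 <- mean_col(e2)
  raw <- mean_col(e0)
  # same seeds give the same scenes, so the observed gap equals the gap
  # predicted by applying the two stain matrices to the mean raw color
  pred_gap <- as.numeric((d1 - d2) %*% raw)
  expect_equal(m1 - m2, pred_gap, tolerance = 1e-8)
  expect_gt(max(abs(m1 - m2)), 0.005)
})

test_that("blank class renders background plus site transform only", {
  eff <- a_site_effect(alpha = 1, seed = 6)[[1]]
  p <- render_patch(0, eff, patch_px = 48, seed = 1)
  expect_false(any(attr(p, "nucleus_mask")))
  bg <- c(0.94, 0.91, 0.93)
  field <- band_limited_noise(48, eff$noise_texture_seed)
  expected <- sapply(1:3, function(ch)
    sum(eff$stain_matrix[ch, ] * bg)) |>
    rep(each = 48 * 48) |>
    array(dim = c(48, 48, 3))
  expected <- expected + eff$noise_amplitude *
    array(rep(as.numeric(field), 3), dim = c(48, 48, 3))
  expected <- pmin(pmax(expected, 0), 1)
  expect_equal(unclass(p), expected, ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("histogram equalization exposes faint noise and is idempotent", {
  # constant gray patch passes through unchanged
  gray <- array(0.5, dim = c(32, 32, 3))
  expect_equal(amplify_noise(gray), gray, ignore_attr = TRUE)

  # faint site noise on a bright background: variance must strictly grow
  eff <- a_site_effect(alpha = 0.2, seed = 8)[[1]]
  p <- render_patch(0, eff, patch_px = 48, seed = 3)
  eq <- amplify_noise(p)
  for (ch in 1:3)
    expect_gt(var(as.numeric(eq[, , ch])), var(as.numeric(p[, , ch])))

  # applying twice equals applying once, on 10 generated patches
  eff1 <- a_site_effect(alpha = 1, seed = 9)[[1]]
  for (i in 1:10) {
    q <- render_patch(1 + i %% 2, eff1, patch_px = 32, seed = i)
    once <- amplify_noise(q)
    expect_equal(amplify_noise(once), once, tolerance = 1e-12)
  }
})

test_that("at zero alpha, sites are statistically indistinguishable", {
  eff <- a_site_effect(alpha = 0, seed = 10)
  pvals <- vapply(1:100, function(run) {
    means <- function(e, off) vapply(1:8, function(i)
      mean(render_patch(1, e, patch_px = 32, seed = off + i)), numeric(1))
    a <- means(eff[[1]], run * 100)
    b <- means(eff[[2]], run * 100 + 50)
    stats::t.test(a, b)$p.value
  }, numeric(1))
  expect_gte(mean(pvals > 0.01), 0.95)
})
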