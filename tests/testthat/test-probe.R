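test_that("splits are patient-aware, stratified, and seeded", {
  m <- generate_cohort(cohort_config(n_sites = 5, n_slides = 120,
                                     patches_per_slide = 2, feature_dim = 4,
                                     multi_slide_patient_frac = 0.15,
                                     seed = 41))$manifest
  plan <- make_split(m, test_fraction = 0.1, seed = 3)
  test_patients <- m$patient_id[m$slide_id %in% plan$test]
  train_patients <- m$patient_id[m$slide_id %in% plan$train]
  expect_length(intersect(test_patients, train_patients), 0)
  # every multi-slide patient is train-only
  multi <- names(which(table(m$patient_id) > 1))
  expect_length(intersect(test_patients, multi), 0)
  # every site appears in the test set (all sites have enough singles here)
  expect_setequal(unique(m$institution[m$slide_id %in% plan$test]),
                  unique(m$institution))

  expect_identical(make_split(m, 0.1, seed = 3)$test, plan$test)
  expect_false(identical(make_split(m, 0.1, seed = 4)$test, plan$test))
})

test_that("a patient owning three slides never reaches the test set", {
  m <- data.frame(
    slide_id = c(sprintf("TCGA-AA-0001-DX%d", 1:3),
                 sprintf("TCGA-AA-%04d-DX1", 2:9),
                 sprintf("TCGA-BB-%04d-DX1", 1:8)),
    patient_id = c(rep("TCGA-AA-0001", 3),
                   sprintf("TCGA-AA-%04d", 2:9),
                   sprintf("TCGA-BB-%04d", 1:8)),
    institution = rep(c("Hosp A", "Hosp B"), c(11, 8)),
    stringsAsFactors = FALSE)
  for (s in 1:10) {
    plan <- make_split(m, test_fraction = 0.2, seed = s)
    expect_length(intersect(plan$test, m$slide_id[m$patient_id == "TCGA-AA-0001"]), 0)
  }
})

test_that("test size tracks the configured fraction", {
  m <- data.frame(slide_id = sprintf("TCGA-%s-%04d-DX1",
                                     rep(c("AA", "BB"), each = 50), 1:100),
                  patient_id = sprintf("TCGA-%s-%04d",
                                       rep(c("AA", "BB"), each = 50), 1:100),
                  institution = rep(c("Hosp A", "Hosp B"), each = 50),
                  stringsAsFactors = FALSE)
  plan <- make_split(m, test_fraction = 0.1, seed = 1)
  expect_length(plan$test, 10)
  expect_length(plan$train, 90)
})

test_that("the probe learns a separable cohort and is reproducible", {
  coh <- strong_cohort()
  st <- sitebias:::stack_features(coh, coh$manifest$slide_id)
  # independent linear oracle first: nearest centroid separates the sites
  cent <- t(sapply(split(seq_along(st$y), st$y),
                   function(i) colMeans(st$x[i, , drop = FALSE])))
  d2 <- outer(rowSums(st$x^2), rowSums(cent^2), "+") - 2 * tcrossprod(st$x, cent)
  expect_gte(mean(rownames(cent)[max.col(-d2)] == st$y), 0.99)

  probe <- train_probe(st$x, st$y, probe_config(seed = 5))
  expect_gte(mean(predict(probe, st$x) == st$y), 0.99)

  probe2 <- train_probe(st$x, st$y, probe_config(seed = 5))
  expect_identical(predict(probe, st$x, type = "prob"),
                   predict(probe2, st$x, type = "prob"))
  expect_error(train_probe(st$x, rep("one", nrow(st$x)), probe_config()),
               "single class")
})

test_that("shuffled labels leave no generalizable site signal", {
  cfg <- cohort_config(n_sites = 5, n_slides = 250, n_classes = 1,
                       patches_per_slide = 20, feature_dim = 32,
                       site_effect_alpha = 2, seed = 31)
  coh <- generate_cohort(cfg)
  st <- sitebias:::stack_features(coh, coh$manifest$slide_id)
  y_sh <- local({ set.seed(1); sample(st$y) })

  # memorization shrinks toward chance as the data grows
  idx_small <- 1:1000
  p_small <- train_probe(st$x[idx_small, ], y_sh[idx_small],
                         probe_config(seed = 2))
  p_big <- train_probe(st$x, y_sh, probe_config(seed = 2))
  acc_small <- mean(predict(p_small, st$x[idx_small, ]) == y_sh[idx_small])
  acc_big <- mean(predict(p_big, st$x) == y_sh)
  expect_lt(acc_big, acc_small)

  # held-out accuracy sits at chance (binomial band, 1000 test patches)
  test_idx <- 4001:5000
  p_tr <- train_probe(st$x[-test_idx, ], y_sh[-test_idx],
                      probe_config(seed = 3))
  acc_te <- mean(predict(p_tr, st$x[test_idx, ]) == y_sh[test_idx])
  expect_lt(abs(acc_te - 0.2), 0.08)
})

test_that("evaluation reports majority-vote slide calls and per-site F1", {
  # craft a perfectly separable 2-site problem with known geometry
  x_tr <- rbind(matrix(rnorm(200, mean = 5), 50),
                matrix(rnorm(200, mean = -5), 50))
  y_tr <- rep(c("Hosp A", "Hosp B"), each = 50)
  probe <- train_probe(x_tr, y_tr, probe_config(seed = 6))

  # slide s1: 2 patches clearly A + 1 patch clearly B -> majority A
  x_te <- rbind(matrix(rnorm(8, mean = 5), 2),
                matrix(rnorm(4, mean = -5), 1),
                matrix(rnorm(12, mean = -5), 3))
  ev <- evaluate_probe(probe, x_te,
                       y = c("Hosp A", "Hosp A", "Hosp A",
                             "Hosp B", "Hosp B", "Hosp B"),
                       slide_ids = c("s1", "s1", "s1", "s2", "s2", "s2"))
  expect_equal(ev$slide_accuracy, 1)
  expect_equal(ev$patch_accuracy, 5 / 6)
  expect_equal(as.numeric(ev$confusion),
               as.numeric(table(factor(c("Hosp A", "Hosp B"),
                                       levels = c("Hosp A", "Hosp B")),
                                factor(c("Hosp A", "Hosp B"),
                                       levels = c("Hosp A", "Hosp B")))))
  expect_equal(ev$per_site$f1, c(1, 1))

  # one-site test set, correctly predicted: accuracy and F1 of that site = 1
  ev1 <- evaluate_probe(probe, matrix(rnorm(8, mean = 5), 2),
                        y = rep("Hosp A", 2), slide_ids = c("u1", "u2"))
  expect_equal(ev1$patch_accuracy, 1)
  expect_equal(ev1$per_site$f1[ev1$per_site$site == "Hosp A"], 1)
})

test_that("a single repeat equals the composed split/train/evaluate run", {
  coh <- strong_cohort()
  cfg <- probe_config(n_repeats = 1, seed = 11)
  rep1 <- repeat_experiment(coh, cfg, scope = "all")

  seed_r <- sitebias:::derive_seed(cfg$seed, 1)
  plan <- suppressWarnings(make_split(coh$manifest, cfg$test_fraction,
                                      seed = seed_r))
  tr <- sitebias:::stack_features(coh, plan$train)
  te <- sitebias:::stack_features(coh, plan$test)
  probe <- train_probe(tr$x,
                       factor(tr$y, levels = sort(unique(coh$manifest$institution))),
                       cfg, seed = sitebias:::derive_seed(seed_r, 1))
  ev <- evaluate_probe(probe, te$x, te$y, te$slide)
  expect_equal(rep1$repeats$patch_accuracy, ev$patch_accuracy)
  expect_equal(rep1$repeats$slide_accuracy, ev$slide_accuracy)
})

test_that("scopes restrict sites and projects as configured", {
  coh <- strong_cohort()
  cfg <- probe_config(n_repeats = 2, seed = 12)
  by_proj <- repeat_experiment(coh, cfg, scope = "per_project")
  expect_setequal(names(by_proj), unique(coh$manifest$project))
  for (r in by_proj) expect_gte(r$mean_slide_accuracy, 0)

  # group scope: with equal shares all sites are in A, B errors out
  expect_s3_class(repeat_experiment(coh, cfg, scope = "groupA"),
                  "probe_report")
  expect_error(repeat_experiment(coh, cfg, scope = "groupB"),
               "fewer than 2 sites")
})
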