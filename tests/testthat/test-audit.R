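test_that("expected same-site counts follow the two analytic forms", {
  # a site with a 20% corpus share expects 1 in 5 results (naive form)
  ev <- expected_same_site(k = 5, n_i = 20, N = 100, q = 10, "naive")
  expect_equal(ev / (10 * 5), 0.20)

  # single-site corpus: self-excluded EV is certainty, q * k
  expect_equal(expected_same_site(k = 3, n_i = 8, N = 8, q = 8,
                                  "self_excluded"), 8 * 3)

  expect_equal(expected_same_site(5, 10, 40, 10, "naive"), 12.5)
  expect_equal(expected_same_site(5, 10, 40, 10, "self_excluded"), 50 * 9 / 39)

  expect_error(expected_same_site(5, 0, 40, 0), "n_i")
  expect_error(expected_same_site(5, 10, 40, 11), "q <= n_i")
  expect_error(expected_same_site(40, 10, 40, 5), "k <= N - 1")
})

toy_results <- function(neighbors_by_query) {
  lapply(names(neighbors_by_query), function(q) {
    nb <- neighbors_by_query[[q]]
    structure(list(query_id = q, k = length(nb),
                   neighbors = data.frame(slide_id = nb,
                                          distance = seq_along(nb) * 0.1,
                                          stringsAsFactors = FALSE),
                   metric = "median_of_min", restricted_to = "PR01",
                   excluded_same_patient = TRUE),
              class = "search_result")
  })
}

toy_manifest <- function(sites) {
  data.frame(slide_id = names(sites), patient_id = names(sites),
             site_code = "xx", institution = unname(sites),
             project = "PR01", stringsAsFactors = FALSE)
}

test_that("observed same-site counts are counted per query site", {
  sites <- c(s1 = "A", s2 = "A", s3 = "A", s4 = "B", s5 = "B", s6 = "B")
  m <- toy_manifest(sites)

  # every neighbor from the query's site: O = q * k
  res <- toy_results(list(s1 = c("s2", "s3"), s2 = c("s1", "s3"),
                          s3 = c("s1", "s2")))
  obs <- observed_same_site(res, m)
  expect_equal(obs$observed[obs$site == "A"], 6L)

  # no neighbor shares the site: O = 0
  res0 <- toy_results(list(s1 = c("s4", "s5"), s2 = c("s5", "s6")))
  obs0 <- observed_same_site(res0, m)
  expect_equal(obs0$observed[obs0$site == "A"], 0L)

  # hand-counted mixed toy: s1 -> {s2,s4}: 1; s4 -> {s5,s1}: 1; s5 -> {s4,s6}: 2
  resm <- toy_results(list(s1 = c("s2", "s4"), s4 = c("s5", "s1"),
                           s5 = c("s4", "s6")))
  obsm <- observed_same_site(resm, m)
  expect_equal(obsm$observed[obsm$site == "A"], 1L)
  expect_equal(obsm$observed[obsm$site == "B"], 3L)
  # conservation: the pair matrix grand total equals all returned neighbors
  expect_equal(sum(attr(obsm, "pair_matrix")), 6)

  expect_error(observed_same_site(toy_results(list(s1 = "zz")), m),
               "unresolvable")
})

test_that("the permutation null matches the self-excluded analytic EV", {
  cfg <- cohort_config(n_sites = 3, n_slides = 45, n_classes = 1,
                       patches_per_slide = 5, feature_dim = 16,
                       site_effect_alpha = 0.3, seed = 51)
  coh <- generate_cohort(cfg)
  rep <- audit_report(coh, k = 4, n_perm = 4000, seed = 6)
  se <- rep$perm_sd / sqrt(attr(rep, "n_perm"))
  expect_true(all(abs(rep$perm_mean - rep$ev_self_excluded) <= 3 * se))
  expect_true(all(rep$p_value >= 0, na.rm = TRUE))
  expect_true(all(rep$p_value <= 1, na.rm = TRUE))
})

test_that("degenerate single-site diagnoses are flagged without a p-value", {
  cfg <- cohort_config(n_sites = 1, n_slides = 8, n_classes = 1,
                       patches_per_slide = 4, feature_dim = 8, seed = 52)
  coh <- generate_cohort(cfg)
  rep <- audit_report(coh, k = 2, n_perm = 100, seed = 1)
  expect_true(all(rep$degenerate))
  expect_true(all(is.na(rep$p_value)))
  expect_equal(rep$observed, rep$q * 2)  # every neighbor is same-site
})

test_that("strong site effects push every modest-share site far above EV", {
  cfg <- cohort_config(n_sites = 6, n_slides = 90, n_classes = 1,
                       patches_per_slide = 10, feature_dim = 32,
                       site_effect_alpha = 3, seed = 53)
  coh <- generate_cohort(cfg)
  rep <- audit_report(coh, k = 5, n_perm = 500, seed = 2)
  expect_true(all(rep$ratio > 4))
  expect_true(all(rep$p_value < 0.05))
  # per-diagnosis conservation of returned pairs
  expect_equal(sum(rep$pairs), nrow(coh$manifest) * 5)
})

test_that("audit report layout and outputs round-trip to disk", {
  coh <- strong_cohort()
  rep <- audit_report(coh, k = 3, n_perm = 200, seed = 3)
  expect_true(all(c("project", "site", "n_i", "N", "q", "k", "observed",
                    "ev_naive", "ev_self_excluded", "ratio", "p_value")
                  %in% names(rep)))
  expect_true(all(rep$observed >= 0 & rep$observed <= rep$q * rep$k))
  expect_true(all(rep$q == rep$n_i))  # every slide of every site is a query

  dir <- withr::local_tempdir()
  write_audit(rep, dir)
  tsv <- read.delim(file.path(dir, "audit.tsv"))
  expect_equal(nrow(tsv), nrow(rep))
  js <- jsonlite::read_json(file.path(dir, "audit.json"))
  expect_equal(js$k, 3)
  expect_equal(length(js$table), nrow(rep))
})
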