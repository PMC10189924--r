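# Retrieval bias audit: observed same-site counts among top-k search
# results versus the no-bias expected value and a permutation null.

#' Expected same-site count under the no-bias null
#'
#' With `q` queries from a site owning `n_i` of the `N` eligible slides,
#' each returning `k` neighbors, the expected number of same-site results
#' under no bias is `q * k * n_i / N` (naive: a site owning 20% of the
#' corpus should own about 1 in 5 results). The self-excluded variant
#' accounts for a query never retrieving itself: each neighbor is one of
#' the other `N - 1` slides, of which `n_i - 1` share the site, giving
#' `q * k * (n_i - 1) / (N - 1)`. The self-excluded form is the one a
#' label-permutation null reproduces exactly.
#'
#' @param k neighbors per query (`k <= N - 1`).
#' @param n_i slides from the site (`1 <= n_i <= N`).
#' @param N eligible corpus size.
#' @param q number of queries from the site (`q <= n_i`).
#' @param variant `"self_excluded"` (default) or `"naive"`.
#' @return expected count (real).
#' @examples
#' expected_same_site(k = 5, n_i = 10, N = 40, q = 10, variant = "naive")
#' @export
expected_same_site <- function(k, n_i, N, q,
                               variant = c("self_excluded", "naive")) {
  variant <- match.arg(variant)
  if (!(n_i >= 1 && n_i <= N)) stop("need 1 <= n_i <= N")
  if (q > n_i) stop("need q <= n_i")
  if (k > N - 1) stop("need k <= N - 1")
  if (variant == "naive") return(q * k * n_i / N)
  if (n_i < 2) return(0)
  q * k * (n_i - 1) / (N - 1)
}

#' Observed same-site counts in search results
#'
#' For each site, counts the (query, neighbor) pairs in which the neighbor
#' comes from the query's own site, over that site's queries. The full
#' query-site by neighbor-site pair contingency table is attached as
#' attribute `"pair_matrix"`; its grand total equals the total number of
#' returned neighbors, of which the per-site observed counts are the
#' diagonal.
#'
#' @param results list of [search_slides()] results, all from one
#'   diagnosis.
#' @param manifest manifest data.frame resolving every slide id.
#' @param site_col site label column (default `"institution"`).
#' @return data.frame with columns `site`, `q` (queries from the site),
#'   `pairs` (neighbors returned for those queries), `observed`.
#' @export
observed_same_site <- function(results, manifest, site_col = "institution") {
  stopifnot(length(results) >= 1, is.data.frame(manifest))
  site_of <- function(ids) {
    idx <- match(ids, manifest$slide_id)
    if (anyNA(idx))
      stop("unresolvable slide id(s): ",
           paste(utils::head(ids[is.na(idx)], 5), collapse = ", "))
    manifest[[site_col]][idx]
  }
  q_sites <- site_of(vapply(results, `[[`, character(1), "query_id"))
  pair_q <- rep(q_sites, vapply(results, function(r) nrow(r$neighbors),
                                integer(1)))
  pair_n <- site_of(unlist(lapply(results, function(r) r$neighbors$slide_id)))
  lev <- sort(unique(c(pair_q, pair_n, q_sites)))
  pm <- table(factor(pair_q, levels = lev), factor(pair_n, levels = lev),
              dnn = c("query_site", "neighbor_site"))
  out <- data.frame(site = lev,
                    q = as.integer(table(factor(q_sites, levels = lev))),
                    pairs = as.integer(rowSums(pm)),
                    observed = as.integer(diag(pm)),
                    stringsAsFactors = FALSE)
  out <- out[out$q > 0, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "pair_matrix") <- pm
  out
}

#' Permutation null for same-site retrieval counts
#'
#' Holds every query's neighbor list fixed and permutes the site labels
#' across the diagnosis's slides, recomputing each site's same-site count
#' `O` per permutation. The two-sided p-value for site `i` is
#' `(1 + #(|O_perm - mean| >= |O_obs - mean|)) / (n_perm + 1)`. A
#' diagnosis with a single site has no permutation distribution; its p is
#' reported as `NA`.
#'
#' @param results list of [search_slides()] results from one diagnosis.
#' @param manifest manifest data.frame covering the diagnosis's slides
#'   (all rows sharing the queries' project form the permutation pool).
#' @param n_perm number of permutations (>= 1000 recommended; smaller
#'   values make the Monte-Carlo error of the p-value substantial).
#' @param seed integer seed.
#' @param site_col site label column.
#' @return list with `observed` (the [observed_same_site()] table plus
#'   columns `perm_mean`, `perm_sd`, `p_value`), `null` (matrix `n_perm x
#'   n_sites` of permuted counts), `n_perm`, `seed`.
#' @export
permutation_null <- function(results, manifest, n_perm = 1000, seed = 1,
                             site_col = "institution") {
  stopifnot(n_perm >= 1)
  obs <- observed_same_site(results, manifest, site_col)
  q_ids <- vapply(results, `[[`, character(1), "query_id")
  proj <- unique(manifest$project[match(q_ids, manifest$slide_id)])
  if (length(proj) != 1)
    stop("results must all come from one diagnosis; got: ",
         paste(proj, collapse = ", "))
  pool <- manifest[manifest$project == proj, , drop = FALSE]
  labels <- pool[[site_col]]
  sites <- sort(unique(labels))

  qi <- match(q_ids, pool$slide_id)
  k_per <- vapply(results, function(r) nrow(r$neighbors), integer(1))
  pair_q <- rep(qi, k_per)
  pair_n <- match(unlist(lapply(results, function(r) r$neighbors$slide_id)),
                  pool$slide_id)
  if (anyNA(pair_n) || anyNA(qi))
    stop("search results reference slides outside the diagnosis pool")

  count_o <- function(lab) {
    same <- lab[pair_q] == lab[pair_n]
    vapply(sites, function(s) sum(same & lab[pair_q] == s), numeric(1))
  }
  null <- with_seed(seed, {
    out <- vapply(seq_len(n_perm), function(p) count_o(sample(labels)),
                  numeric(length(sites)))
    matrix(out, nrow = n_perm, ncol = length(sites), byrow = TRUE)
  })
  colnames(null) <- sites

  obs_all <- setNames(rep(0L, length(sites)), sites)
  obs_all[obs$site] <- obs$observed
  mu <- colMeans(null)
  sdv <- apply(null, 2, sd)
  p <- vapply(sites, function(s) {
    if (length(unique(labels)) < 2) return(NA_real_)
    (1 + sum(abs(null[, s] - mu[s]) >= abs(obs_all[s] - mu[s]))) / (n_perm + 1)
  }, numeric(1))
  obs$perm_mean <- mu[obs$site]
  obs$perm_sd <- sdv[obs$site]
  obs$p_value <- p[obs$site]
  list(observed = obs, null = null, n_perm = as.integer(n_perm), seed = seed)
}

#' Site-bias audit of slide retrieval
#'
#' The full audit: every slide of every site is used as a query within its
#' own diagnosis (project), the top-`k` neighbors are retrieved with the
#' chosen slide distance, and for each (diagnosis, site) the observed
#' same-site count `O` is compared with the analytic expected values and a
#' within-diagnosis label-permutation null. Ratios far above 1 mean the
#' retrieval engine returns same-hospital slides far more often than the
#' site's corpus share explains.
#'
#' @param cohort feature-mode `site_cohort`.
#' @param k neighbors per query (default 5).
#' @param metric `"median_of_min"` (default) or `"mean_pooled"`.
#' @param n_perm permutations per diagnosis (default 1000).
#' @param seed integer seed.
#' @param exclude_same_patient exclude the query patient's other slides
#'   from its corpus (default `TRUE`).
#' @param site_col site label column.
#' @return Object of class `bias_report`: a data.frame with one row per
#'   (diagnosis, site): `project`, `site`, `n_i`, `N`, `q`, `k`, `pairs`,
#'   `observed`, `ev_naive`, `ev_self_excluded`, `ratio`
#'   (observed / self-excluded EV), `perm_mean`, `perm_sd`, `p_value`,
#'   `degenerate` (single-site diagnosis: no p-value). Attributes carry
#'   `k`, `metric`, `n_perm`, `seed`, and the per-diagnosis search results.
#' @export
audit_report <- function(cohort, k = 5,
                         metric = c("median_of_min", "mean_pooled"),
                         n_perm = 1000, seed = 1,
                         exclude_same_patient = TRUE,
                         site_col = "institution") {
  metric <- match.arg(metric)
  stopifnot(inherits(cohort, "site_cohort"), cohort$mode == "features")
  m <- cohort$manifest
  all_results <- list()
  rows <- list()
  for (proj in sort(unique(m$project))) {
    sub <- m[m$project == proj, , drop = FALSE]
    N <- nrow(sub)
    if (N < 2) {
      message("diagnosis ", proj, " has a single slide; skipped")
      next
    }
    d <- slide_distance_matrix(cohort$features[sub$slide_id], metric)
    results <- lapply(seq_len(N), function(i) {
      elig <- rep(TRUE, N)
      elig[i] <- FALSE
      if (exclude_same_patient)
        elig <- elig & sub$patient_id != sub$patient_id[i]
      ids <- sub$slide_id[elig]
      di <- d[i, elig]
      ord <- order(di, ids)[seq_len(min(k, length(ids)))]
      structure(list(query_id = sub$slide_id[i], k = as.integer(k),
                     neighbors = data.frame(slide_id = ids[ord],
                                            distance = unname(di[ord]),
                                            stringsAsFactors = FALSE),
                     metric = metric, restricted_to = proj,
                     excluded_same_patient = exclude_same_patient),
                class = "search_result")
    })
    all_results[[proj]] <- results
    pn <- permutation_null(results, m, n_perm = n_perm,
                           seed = derive_seed(seed, match(proj, sort(unique(m$project)))),
                           site_col = site_col)
    tab <- pn$observed
    degenerate <- length(unique(sub[[site_col]])) < 2
    tab$n_i <- as.integer(table(sub[[site_col]])[tab$site])
    tab$ev_naive <- vapply(seq_len(nrow(tab)), function(i)
      expected_same_site(k, tab$n_i[i], N, tab$q[i], "naive"), numeric(1))
    tab$ev_self_excluded <- vapply(seq_len(nrow(tab)), function(i)
      expected_same_site(k, tab$n_i[i], N, tab$q[i], "self_excluded"),
      numeric(1))
    tab$ratio <- ifelse(tab$ev_self_excluded > 0,
                        tab$observed / tab$ev_self_excluded, NA_real_)
    rows[[proj]] <- data.frame(project = proj, site = tab$site,
                               n_i = tab$n_i, N = N, q = tab$q,
                               k = as.integer(k), pairs = tab$pairs,
                               observed = tab$observed,
                               ev_naive = tab$ev_naive,
                               ev_self_excluded = tab$ev_self_excluded,
                               ratio = tab$ratio,
                               perm_mean = tab$perm_mean,
                               perm_sd = tab$perm_sd,
                               p_value = tab$p_value,
                               degenerate = degenerate,
                               stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) stop("no diagnosis with >= 2 slides")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "k") <- as.integer(k)
  attr(out, "metric") <- metric
  attr(out, "n_perm") <- as.integer(n_perm)
  attr(out, "seed") <- seed
  attr(out, "results") <- all_results
  class(out) <- c("bias_report", "data.frame")
  out
}

#' @export
print.bias_report <- function(x, ...) {
  cat("<bias_report> k = ", attr(x, "k"), ", metric = ", attr(x, "metric"),
      ", ", attr(x, "n_perm"), " permutations\n", sep = "")
  cols <- c("project", "site", "n_i", "N", "observed", "ev_self_excluded",
            "ratio", "p_value")
  print.data.frame(x[, cols], digits = 3, row.names = FALSE)
  invisible(x)
}

#' Bar chart of observed vs expected same-site counts
#'
#' One bar pair per (diagnosis, site): the observed same-site count next
#' to the self-excluded expected value, faceted by diagnosis. Requires
#' ggplot2.
#'
#' @param report a [audit_report()].
#' @return a ggplot object.
#' @export
plot_bias_report <- function(report) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_bias_report requires ggplot2")
  df <- rbind(
    data.frame(project = report$project, site = report$site,
               what = "observed", count = report$observed),
    data.frame(project = report$project, site = report$site,
               what = "expected", count = report$ev_self_excluded))
  ggplot2::ggplot(df, ggplot2::aes(x = site, y = count, fill = what)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~project, scales = "free") +
    ggplot2::labs(x = "acquisition site", y = "same-site results in top-k",
                  fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
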