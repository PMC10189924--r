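# Slide-to-slide retrieval on bags of patch features.

#' Median-of-min distance between two slides
#'
#' Directional set distance between two bags of patch features: for each
#' patch `a` of slide `A`, take the minimum Euclidean distance to any
#' patch of slide `B`; the slide distance is the median of those minima.
#' Not symmetric in general. The `"lower"` median convention (default)
#' returns the lower-middle order statistic for even patch counts, so the
#' value is always an attained min-distance; `"midpoint"` averages the two
#' middle values.
#'
#' @param a,b `slide_features` or numeric matrices (rows = patches).
#' @param median_type `"lower"` (default) or `"midpoint"`.
#' @return nonnegative scalar.
#' @examples
#' a <- matrix(c(0, 0, 1, 1), 2, 2, byrow = TRUE)
#' median_of_min_distance(a, a)  # 0
#' @export
median_of_min_distance <- function(a, b, median_type = c("lower", "midpoint")) {
  median_type <- match.arg(median_type)
  a <- as_feature_matrix(a); b <- as_feature_matrix(b)
  if (nrow(a) == 0 || nrow(b) == 0) stop("empty feature matrix")
  stopifnot(ncol(a) == ncol(b))
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  mins <- sqrt(pmax(apply(d2, 1, min), 0))
  lower_median(mins, median_type)
}

lower_median <- function(v, median_type = "lower") {
  v <- sort(v)
  n <- length(v)
  if (median_type == "midpoint" && n %% 2 == 0)
    return((v[n / 2] + v[n / 2 + 1]) / 2)
  v[(n + 1) %/% 2]
}

#' Mean-pooled distance between two slides
#'
#' Euclidean distance between the column-mean patch feature vectors of the
#' two slides. Symmetric.
#'
#' @inheritParams median_of_min_distance
#' @return nonnegative scalar.
#' @export
mean_pooled_distance <- function(a, b) {
  a <- as_feature_matrix(a); b <- as_feature_matrix(b)
  if (nrow(a) == 0 || nrow(b) == 0) stop("empty feature matrix")
  sqrt(sum((colMeans(a) - colMeans(b))^2))
}

# All-pairs slide distance matrix for a feature-mode cohort subset.
# Rows are queries (directional for median_of_min).
slide_distance_matrix <- function(features, metric = c("median_of_min",
                                                       "mean_pooled"),
                                  median_type = "lower") {
  metric <- match.arg(metric)
  if (metric == "mean_pooled") {
    pooled <- t(vapply(features, colMeans, numeric(ncol(features[[1]]))))
    return(as.matrix(stats::dist(pooled)))
  }
  counts <- vapply(features, nrow, integer(1))
  x <- do.call(rbind, features)
  starts <- c(0L, cumsum(counts)[-length(counts)])
  d <- cpp_slide_distances(x, starts, counts, median_type == "lower")
  dimnames(d) <- list(names(features), names(features))
  d
}

#' Retrieve the k most similar slides for a query
#'
#' Ranks the corpus by the chosen slide distance, after restricting to the
#' query's primary diagnosis (project) and excluding the query itself and,
#' by default, other slides of the query's patient. Distance ties are
#' broken by lexicographic slide id, making the ranking deterministic.
#'
#' @param query_id slide id present in the cohort.
#' @param cohort feature-mode `site_cohort`.
#' @param k neighbors to return (default 5); capped at the eligible corpus
#'   size.
#' @param metric `"median_of_min"` (default) or `"mean_pooled"`.
#' @param restrict_to_diagnosis only consider slides with the query's
#'   project (default `TRUE`).
#' @param exclude_same_patient drop other slides of the query's patient
#'   (default `TRUE`).
#' @param median_type see [median_of_min_distance()].
#' @return Object of class `search_result`: `query_id`, `k`, `neighbors`
#'   (data.frame `slide_id`, `distance`, ascending), `metric`,
#'   `restricted_to`, `excluded_same_patient`.
#' @export
search_slides <- function(query_id, cohort, k = 5,
                          metric = c("median_of_min", "mean_pooled"),
                          restrict_to_diagnosis = TRUE,
                          exclude_same_patient = TRUE,
                          median_type = "lower") {
  metric <- match.arg(metric)
  stopifnot(inherits(cohort, "site_cohort"), cohort$mode == "features")
  m <- cohort$manifest
  qrow <- match(query_id, m$slide_id)
  if (is.na(qrow)) stop("unknown slide id: ", query_id)
  eligible <- m$slide_id != query_id
  restricted_to <- NA_character_
  if (restrict_to_diagnosis) {
    eligible <- eligible & m$project == m$project[qrow]
    restricted_to <- m$project[qrow]
  }
  if (exclude_same_patient)
    eligible <- eligible & m$patient_id != m$patient_id[qrow]
  ids <- m$slide_id[eligible]
  if (length(ids) == 0) stop("empty eligible corpus for query ", query_id)
  qf <- cohort$features[[query_id]]
  dist_fun <- if (metric == "median_of_min") {
    function(b) median_of_min_distance(qf, b, median_type)
  } else {
    function(b) mean_pooled_distance(qf, b)
  }
  d <- vapply(cohort$features[ids], dist_fun, numeric(1))
  ord <- order(d, ids)[seq_len(min(k, length(ids)))]
  structure(list(query_id = query_id, k = as.integer(k),
                 neighbors = data.frame(slide_id = ids[ord],
                                        distance = unname(d[ord]),
                                        stringsAsFactors = FALSE),
                 metric = metric, restricted_to = restricted_to,
                 excluded_same_patient = exclude_same_patient),
            class = "search_result")
}

#' @export
print.search_result <- function(x, ...) {
  cat("<search_result> query ", x$query_id, " (", x$metric, ", k = ", x$k,
      ")\n", sep = "")
  print(x$neighbors, row.names = FALSE)
  invisible(x)
}
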