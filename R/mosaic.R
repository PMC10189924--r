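# Mosaic patch sampling: RGB-histogram clustering at low magnification,
# proportional budget allocation, and a cellularity filter.

#' Concatenated per-channel RGB histograms
#'
#' One feature row per patch: each channel's histogram over `bins` equal
#' bins of \[0, 1\], L1-normalized per channel, concatenated (length
#' `3 * bins`).
#'
#' @param patches list of `h x w x 3` arrays in \[0, 1\].
#' @param bins bins per channel (default 16).
#' @return `length(patches) x (3 * bins)` matrix; rows of each channel
#'   block sum to 1.
#' @export
rgb_histograms <- function(patches, bins = 16) {
  stopifnot(length(patches) >= 1, bins >= 2)
  t(vapply(patches, function(p) {
    unlist(lapply(1:3, function(ch) {
      v <- pmin(pmax(p[, , ch], 0), 1)
      idx <- pmin(floor(v * bins) + 1L, bins)
      h <- tabulate(idx, nbins = bins)
      h / sum(h)
    }))
  }, numeric(3 * bins)))
}

#' Cluster low-magnification patches by RGB histogram
#'
#' Centroid-based (k-means) partition of histogram rows into at most
#' `n_clusters` nonempty clusters, with 10 restarts under a fixed seed for
#' determinism. Exact duplicate rows always share a label; when there are
#' no more distinct histograms than clusters, every distinct histogram
#' becomes its own cluster (logged).
#'
#' @param histograms matrix from [rgb_histograms()].
#' @param n_clusters target cluster count (default 9).
#' @param seed integer seed.
#' @return integer vector of cluster labels in `1..n_clusters`.
#' @export
cluster_patches <- function(histograms, n_clusters = 9, seed = 1) {
  stopifnot(is.matrix(histograms), n_clusters >= 1)
  # k-means needs distinct centers; collapse exact duplicates first
  key <- apply(histograms, 1, paste, collapse = "\r")
  uniq <- !duplicated(key)
  nu <- sum(uniq)
  if (nu <= n_clusters) {
    if (nrow(histograms) <= n_clusters)
      message("cluster_patches: ", nrow(histograms), " patches <= ",
              n_clusters, " clusters; using singleton clusters")
    labels_uniq <- seq_len(nu)
  } else {
    fit <- with_seed(seed,
                     kmeans(histograms[uniq, , drop = FALSE],
                            centers = n_clusters, nstart = 10,
                            iter.max = 50))
    labels_uniq <- fit$cluster
  }
  labels_uniq[match(key, key[uniq])]
}

#' Allocate a patch budget proportionally to cluster sizes
#'
#' Largest-remainder apportionment of `min(budget, sum(sizes))` patches,
#' with each cluster capped at its own size; spill from capped clusters is
#' redistributed by remainder order, so counts always sum to
#' `min(budget, sum(sizes))`.
#'
#' @param cluster_sizes nonnegative integer vector, not all zero.
#' @param budget total patches to draw.
#' @return integer vector of per-cluster counts.
#' @examples
#' allocate_budget(c(90, 10), 10)
#' @export
allocate_budget <- function(cluster_sizes, budget) {
  stopifnot(all(cluster_sizes >= 0), sum(cluster_sizes) > 0, budget >= 0)
  target <- min(budget, sum(cluster_sizes))
  quota <- cluster_sizes / sum(cluster_sizes) * target
  counts <- pmin(floor(quota), cluster_sizes)
  rem <- quota - floor(quota)
  ord <- order(rem, decreasing = TRUE)
  while (sum(counts) < target) {
    open <- ord[counts[ord] < cluster_sizes[ord]]
    counts[open[1]] <- counts[open[1]] + 1
  }
  as.integer(counts)
}

#' Cellularity score of a patch
#'
#' Fraction of pixels that look nuclear: luminance (channel mean) below
#' 0.55 of the dynamic range and blue-to-red ratio of at least 1
#' (hematoxylin stains nuclei dark blue-purple; eosin background is bright
#' and red-shifted). The ratio is regularized so that near-black pixels —
#' ratio 1 — count as nuclear. Both cuts are package conventions — exposed
#' as arguments — since no standard formula exists.
#'
#' @param patch `h x w x 3` array in \[0, 1\].
#' @param darkness_cut luminance threshold (default 0.55).
#' @param blue_red_min minimum blue/red ratio (default 1, inclusive).
#' @return fraction in \[0, 1\].
#' @export
cellularity_score <- function(patch, darkness_cut = 0.55, blue_red_min = 1) {
  stopifnot(length(dim(patch)) == 3, dim(patch)[3] == 3)
  lum <- (patch[, , 1] + patch[, , 2] + patch[, , 3]) / 3
  br <- (patch[, , 3] + 1e-8) / (patch[, , 1] + 1e-8)
  mean(lum < darkness_cut & br >= blue_red_min)
}

#' Mosaic sampling configuration
#'
#' @param n_clusters histogram clusters (default 9).
#' @param histogram_bins bins per channel (default 16).
#' @param budget patches per slide (default 55).
#' @param cellularity_threshold minimum [cellularity_score()] for a patch
#'   to be eligible (default 0.1).
#' @param cluster_level,sample_level magnification tags recorded in the
#'   output (defaults "5x" and "20x").
#' @param seed integer seed.
#' @return list of class `mosaic_config`.
#' @export
mosaic_config <- function(n_clusters = 9, histogram_bins = 16, budget = 55,
                          cellularity_threshold = 0.1,
                          cluster_level = "5x", sample_level = "20x",
                          seed = 1) {
  stopifnot(n_clusters >= 1, budget >= 1,
            cellularity_threshold >= 0, cellularity_threshold <= 1)
  structure(list(n_clusters = as.integer(n_clusters),
                 histogram_bins = as.integer(histogram_bins),
                 budget = as.integer(budget),
                 cellularity_threshold = cellularity_threshold,
                 cluster_level = cluster_level,
                 sample_level = sample_level,
                 seed = as.integer(seed)),
            class = "mosaic_config")
}

#' Sample a representative patch mosaic from one slide
#'
#' Pipeline: discard patches below the cellularity threshold, cluster the
#' survivors by RGB histogram, allocate the budget proportionally to
#' cluster sizes, then sample uniformly without replacement within each
#' cluster (seeded). The filter runs before allocation so budgets reflect
#' eligible patches only.
#'
#' @param slide list with `slide_id`, `patches` (list of rasters) and
#'   `coords` (data.frame `x`, `y`, `level`), as stored in an image-mode
#'   `site_cohort`.
#' @param config a [mosaic_config()].
#' @return Object of class `patch_set`: `slide_id`, selected `indices`
#'   (into the slide's patch list), `coords`, `patches`, `cluster_labels`,
#'   and the magnification tags.
#' @export
sample_mosaic <- function(slide, config = mosaic_config()) {
  stopifnot(is.list(slide), !is.null(slide$slide_id),
            length(slide$patches) >= 1, inherits(config, "mosaic_config"))
  scores <- vapply(slide$patches, cellularity_score, numeric(1))
  eligible <- which(scores >= config$cellularity_threshold)
  if (length(eligible) == 0)
    stop("no patch of slide ", slide$slide_id,
         " passes the cellularity filter (threshold ",
         config$cellularity_threshold, ")")
  hists <- rgb_histograms(slide$patches[eligible], bins = config$histogram_bins)
  labels <- cluster_patches(hists, config$n_clusters,
                            seed = derive_seed(config$seed, 1))
  sizes <- tabulate(labels, nbins = max(labels))
  counts <- allocate_budget(sizes, config$budget)
  picked <- with_seed(derive_seed(config$seed, 2), {
    unlist(lapply(seq_along(counts), function(cl) {
      members <- eligible[labels == cl]
      if (counts[cl] == 0) return(integer(0))
      if (counts[cl] >= length(members)) return(members)
      sample(members, counts[cl])
    }))
  })
  picked <- sort(picked)
  structure(list(slide_id = slide$slide_id,
                 indices = picked,
                 coords = slide$coords[picked, , drop = FALSE],
                 patches = slide$patches[picked],
                 cluster_labels = labels[match(picked, eligible)],
                 cluster_level = config$cluster_level,
                 sample_level = config$sample_level),
            class = "patch_set")
}

#' @export
print.patch_set <- function(x, ...) {
  cat("<patch_set> slide ", x$slide_id, ": ", length(x$indices),
      " patches at ", x$sample_level, "\n", sep = "")
  invisible(x)
}
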