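#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the RNG seed, evaluates `expr`, and restores the caller's RNG state,
#' so package functions never perturb the global random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}

# Deterministic stream splitting: derive a child seed from (seed, index).
# Arithmetic kept in doubles; result always fits a 32-bit signed integer.
derive_seed <- function(seed, index) {
  as.integer(((as.numeric(seed) + 1) * 1000003 + as.numeric(index) * 7919) %%
               2147483629)
}

#' Largest-remainder apportionment
#'
#' Allocates `total` integer units proportionally to `shares`. Each count
#' differs from its exact quota by strictly less than one unit and counts
#' always sum to `total`. Ties in fractional remainders are broken by index
#' order, making the allocation deterministic.
#'
#' @param shares nonnegative numeric vector (need not sum to 1).
#' @param total nonnegative integer total to apportion.
#' @return Integer vector of counts summing to `total`.
#' @examples
#' largest_remainder(c(0.25, 0.25, 0.25, 0.25), 40)
#' largest_remainder(c(7, 5, 3), 5)
#' @export
largest_remainder <- function(shares, total) {
  stopifnot(is.numeric(shares), all(shares >= 0), sum(shares) > 0,
            length(total) == 1L, total >= 0)
  quota <- shares / sum(shares) * total
  counts <- floor(quota)
  rem <- quota - counts
  deficit <- round(total - sum(counts))
  if (deficit > 0) {
    take <- order(rem, decreasing = TRUE)[seq_len(deficit)]
    counts[take] <- counts[take] + 1
  }
  as.integer(counts)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# base-36 two-character site codes: supports up to 1296 sites
site_code_for <- function(i) {
  chars <- c(0:9, LETTERS)
  paste0(chars[(i - 1) %/% 36 + 1], chars[(i - 1) %% 36 + 1])
}
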