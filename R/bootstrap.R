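#' Bootstrap resampling plan
#'
#' Describes how a dataset is split into an ensemble of resampled subsets:
#' `k` subsets of `n` rows each, drawn uniformly at random with replacement.
#' With-replacement draws from the empirical distribution are the bootstrap
#' and are what makes `n` larger than the source dataset legal.
#'
#' @param k number of subsets (>= 1).
#' @param n rows per subset (>= 1); `NULL` means "as many rows as the source
#'   dataset", resolved when the plan is applied.
#' @param seed integer master seed; per-subset seeds are derived from it (see
#'   [bootstrap_subsets()]).
#' @return an object of class `resample_plan`.
#' @export
resample_plan <- function(k = 100L, n = NULL, seed = 1L) {
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("k must be >= 1")
  if (!is.null(n)) {
    n <- as.integer(n)
    if (is.na(n) || n < 1L) stop("n must be >= 1")
  }
  structure(list(k = k, n = n, seed = as.integer(seed)),
            class = "resample_plan")
}

#' Bootstrap subsets of a categorical dataset
#'
#' Draws `plan$k` datasets of `plan$n` rows each, every row sampled uniformly
#' with replacement from the rows of `D`. Subsets are reproducible
#' independently of one another: the master seed initialises one RNG stream
#' from which `k` per-subset seeds are drawn up front, and subset `i` is
#' generated under its own seed. Two calls with the same plan are identical.
#'
#' @param D a [tab_data] (or coercible data.frame) with at least one row.
#' @param plan a [resample_plan]; a `NULL` `n` resolves to `D$n_rows`.
#' @return list of `k` [tab_data] objects sharing `D`'s variables and
#'   categories.
#' @export
bootstrap_subsets <- function(D, plan = resample_plan()) {
  D <- as_tab_data(D)
  if (D$n_rows < 1L) stop("cannot resample an empty dataset")
  stopifnot(inherits(plan, "resample_plan"))
  n <- if (is.null(plan$n)) D$n_rows else plan$n
  subset_seeds <- derive_seeds(plan$seed, plan$k)
  lapply(seq_len(plan$k), function(i) with_seed(
    subset_seeds[i],
    tab_rows(D, sample.int(D$n_rows, n, replace = TRUE))))
}

# Evaluate expr under a fixed seed, restoring the caller's RNG state after.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# One master seed -> k child seeds, each < 2^31, via a dedicated RNG stream.
derive_seeds <- function(seed, k) {
  with_seed(seed, sample.int(.Machine$integer.max, k))
}
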