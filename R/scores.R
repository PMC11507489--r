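#' Score configuration for structure search
#'
#' @param score `"bdeu"` (default) or `"bic"`.
#' @param ess equivalent sample size of the BDeu prior (> 0); ignored by BIC.
#' @param max_parents in-degree cap per node; `Inf` (default) leaves it
#'   unbounded, which is safe at the network sizes targeted here.
#' @return an object of class `score_config`.
#' @export
score_config <- function(score = c("bdeu", "bic"), ess = 1, max_parents = Inf) {
  score <- match.arg(score)
  if (!is.numeric(ess) || ess <= 0) stop("ess must be > 0")
  structure(list(score = score, ess = ess, max_parents = max_parents),
            class = "score_config")
}

# Joint parent-configuration index (1-based) for each row; q = number of
# parent configurations. Parents indexed by column positions in D$codes.
parent_config_index <- function(D, pa_idx) {
  n <- D$n_rows
  if (length(pa_idx) == 0L)
    return(list(idx = rep.int(1L, n), q = 1L))
  idx <- rep.int(0L, n)
  q <- 1L
  for (p in pa_idx) {
    idx <- idx + (D$codes[, p] - 1L) * q
    q <- q * length(D$categories[[p]])
  }
  list(idx = idx + 1L, q = q)
}

# Child-by-parent-configuration count matrix (r x q).
family_counts <- function(D, child, parents) {
  ci <- match(child, D$variables)
  pi <- match(parents, D$variables)
  if (anyNA(c(ci, pi))) stop("variable not present in dataset")
  r <- length(D$categories[[ci]])
  pc <- parent_config_index(D, pi)
  joint <- (pc$idx - 1L) * r + D$codes[, ci]
  matrix(tabulate(joint, nbins = r * pc$q), nrow = r)
}

# Per-family scores: decomposable, summed over nodes by the *_score wrappers.
family_bic <- function(counts, n_total) {
  nj <- colSums(counts)
  pos <- counts > 0
  ll <- sum(counts[pos] * log(counts[pos] /
                                rep(nj, each = nrow(counts))[pos]))
  npar <- (nrow(counts) - 1L) * ncol(counts)
  ll - 0.5 * log(n_total) * npar
}

family_bdeu <- function(counts, ess) {
  q <- ncol(counts)
  r <- nrow(counts)
  aj <- ess / q
  ajc <- ess / (q * r)
  nj <- colSums(counts)
  sum(lgamma(aj) - lgamma(aj + nj)) +
    sum(lgamma(ajc + counts) - lgamma(ajc))
}

#' Bayesian information criterion of a DAG on discrete data
#'
#' Decomposable score: for each node, the maximized multinomial log-likelihood
#' of the node given its parents minus `0.5 * log(n) * d`, where `d` is the
#' number of free parameters `(r - 1) * q` (`r` child categories, `q` parent
#' configurations). Higher is better.
#'
#' @param g a [dag] whose nodes are variables of `D`.
#' @param D a [tab_data] (or coercible).
#' @return the score (numeric scalar).
#' @export
bic_score <- function(g, D) {
  D <- as_tab_data(D)
  stopifnot(inherits(g, "dag"))
  sum(vapply(g$nodes, function(v)
    family_bic(family_counts(D, v, parents(g, v)), D$n_rows), 0))
}

#' BDeu score of a DAG on discrete data
#'
#' Log marginal likelihood under the Bayesian Dirichlet equivalent uniform
#' prior with equivalent sample size `ess`: per node and parent configuration,
#' a ratio of gamma functions with hyperparameters `ess / (q * r)`. On an
#' empty dataset every term cancels and the score is 0. Higher is better.
#'
#' @inheritParams bic_score
#' @param ess equivalent sample size (> 0).
#' @return the score (numeric scalar).
#' @export
bdeu_score <- function(g, D, ess = 1) {
  D <- as_tab_data(D)
  stopifnot(inherits(g, "dag"))
  if (!is.numeric(ess) || ess <= 0) stop("ess must be > 0")
  sum(vapply(g$nodes, function(v)
    family_bdeu(family_counts(D, v, parents(g, v)), ess), 0))
}

# Memoising family scorer bound to one dataset + config; key: child|parents.
make_family_scorer <- function(D, cfg) {
  cache <- new.env(parent = emptyenv())
  function(child, pa) {
    pa <- sort(pa)
    key <- paste(child, paste(pa, collapse = ","), sep = "|")
    val <- cache[[key]]
    if (is.null(val)) {
      counts <- family_counts(D, child, pa)
      val <- if (cfg$score == "bic") family_bic(counts, D$n_rows)
             else family_bdeu(counts, cfg$ess)
      cache[[key]] <- val
    }
    val
  }
}
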