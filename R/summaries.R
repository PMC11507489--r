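#' Edge existence and direction summary
#'
#' Decomposes the three-state posterior of a pair into two Beta posteriors by
#' Dirichlet aggregation: existence merges the two directed states against
#' absence, `Beta(alpha_left + alpha_right, alpha_none)`; direction is the
#' probability of the right-directed state given that the edge exists,
#' `Beta(alpha_right, alpha_left)`. Intervals are equal-tailed at the
#' posterior's level.
#'
#' @param posterior an `edge_posterior`.
#' @return an object of class `exist_direction` with fields `exists_mean`,
#'   `exists_interval`, `direction_mean`, `direction_interval`, `level`.
#' @export
existence_direction <- function(posterior) {
  stopifnot(inherits(posterior, "edge_posterior"))
  a <- posterior$alpha
  level <- posterior$level
  q <- c((1 - level) / 2, (1 + level) / 2)
  structure(list(
    exists_mean = unname((a["left"] + a["right"]) / sum(a)),
    exists_interval = stats::qbeta(q, a["left"] + a["right"], a["none"]),
    direction_mean = unname(a["right"] / (a["left"] + a["right"])),
    direction_interval = stats::qbeta(q, a["right"], a["left"]),
    level = level), class = "exist_direction")
}

#' Most probable edge state
#'
#' The state (left / none / right) with the largest posterior mean. An exact
#' tie for the maximum is resolved to `"none"`: without a clear winner no
#' edge is asserted.
#'
#' @param posterior an `edge_posterior`.
#' @return one of `"left"`, `"none"`, `"right"`.
#' @export
map_state <- function(posterior) {
  m <- posterior$mean
  top <- names(m)[m == max(m)]
  if (length(top) > 1L) "none" else top
}

#' Maximum a posteriori summary graph
#'
#' Builds the thresholded MAP graph from a credibility report: every pair
#' whose edge-existence posterior mean reaches `threshold` contributes one
#' directed edge, oriented towards the direction with the larger posterior
#' mean. Pairs are treated independently, so the result may contain cycles
#' and is deliberately not validated for acyclicity. The default threshold is
#' the 75% credibility level used for edge selection.
#'
#' @param report a `credibility_report` (see [edge_credibility()]).
#' @param threshold existence-probability cutoff in `[0, 1]`, applied to the
#'   posterior mean of edge existence.
#' @return a [digraph] over the report's variables.
#' @export
map_graph <- function(report, threshold = 0.75) {
  stopifnot(inherits(report, "credibility_report"))
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]")
  edges <- NULL
  for (p in report$pairs) {
    if (p$summary$exists_mean < threshold) next
    m <- p$posterior$mean
    if (m["right"] >= m["left"]) edges <- rbind(edges, p$posterior$pair)
    else edges <- rbind(edges, rev(p$posterior$pair))
  }
  digraph(report$variables, edges)
}

#' Beta-Binomial per-arc baseline
#'
#' The simpler credibility model the three-state posterior improves on: every
#' ordered pair (a, b), a != b, is modelled independently with a Binomial
#' likelihood on "graph contains a -> b" and a `Beta(prior_a, prior_b)` prior,
#' giving `n^2 - n` independent posteriors (20 for 5 variables). Because each
#' direction of a pair is treated as a separate event, the occurrence mass of
#' an undirected association is split across two distributions, which is
#' precisely the defect the Dirichlet-Multinomial model repairs. An arc is
#' `selected` when its posterior mean exceeds 0.5 (present in more than half
#' of the ensemble).
#'
#' @param ensemble non-empty list of [dag] objects.
#' @param variables variable names; defaults to the union of node sets.
#' @param prior_a,prior_b Beta prior parameters (default uniform
#'   `Beta(1, 1)`; `prior_a = prior_b = 0.5` gives Jeffreys).
#' @param level credible level for the equal-tailed interval.
#' @return data.frame with one row per ordered pair: `from`, `to`, `count`,
#'   `k`, `shape1`, `shape2`, `mean`, `low`, `high`, `selected`.
#' @export
beta_binomial_posteriors <- function(ensemble, variables = NULL,
                                     prior_a = 1, prior_b = 1, level = 0.95) {
  if (!length(ensemble)) stop("ensemble must be non-empty")
  if (prior_a <= 0 || prior_b <= 0) stop("prior parameters must be > 0")
  if (is.null(variables))
    variables <- sort(unique(unlist(lapply(ensemble, `[[`, "nodes"))))
  variables <- sort(as.character(variables))
  k <- length(ensemble)
  grid <- expand.grid(to = variables, from = variables,
                      stringsAsFactors = FALSE)[, 2:1]
  grid <- grid[grid$from != grid$to, ]
  grid <- grid[order(grid$from, grid$to), ]
  key <- paste(grid$from, grid$to, sep = "\r")
  count <- integer(length(key))
  for (g in ensemble) {
    if (nrow(g$edges))
      count <- count + (key %in% paste(g$edges[, 1], g$edges[, 2], sep = "\r"))
  }
  shape1 <- prior_a + count
  shape2 <- prior_b + k - count
  q <- c((1 - level) / 2, (1 + level) / 2)
  data.frame(
    from = grid$from, to = grid$to, count = as.integer(count), k = k,
    shape1 = shape1, shape2 = shape2,
    mean = shape1 / (shape1 + shape2),
    low = stats::qbeta(q[1], shape1, shape2),
    high = stats::qbeta(q[2], shape1, shape2),
    selected = shape1 / (shape1 + shape2) > 0.5,
    row.names = NULL, stringsAsFactors = FALSE)
}
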