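#' Edge-state census of a network ensemble
#'
#' For every unordered variable pair, counts how often the ensemble shows a
#' left-directed edge, no edge, or a right-directed edge. Pairs are stored in
#' canonical orientation `from < to` (lexicographic), so `right` always means
#' the edge from the lexicographically smaller to the larger variable and
#' `left` the opposite direction. All pairs are emitted, including pairs never
#' connected in any network, so a posterior exists for every pair.
#'
#' @param ensemble non-empty list of [dag] objects.
#' @param variables character vector of variable names covering every node in
#'   the ensemble; defaults to the union of node sets, sorted.
#' @return an object of class `edge_census`: a data.frame with columns
#'   `from`, `to`, `left`, `none`, `right` (one row per pair,
#'   `choose(length(variables), 2)` rows) and attribute `k` (ensemble size).
#'   Rows satisfy `left + none + right == k`.
#' @export
count_edge_states <- function(ensemble, variables = NULL) {
  if (!length(ensemble)) stop("ensemble must be non-empty")
  if (!all(vapply(ensemble, inherits, NA, "dag")))
    stop("ensemble must be a list of dag objects")
  if (is.null(variables))
    variables <- sort(unique(unlist(lapply(ensemble, `[[`, "nodes"))))
  variables <- as.character(variables)
  for (g in ensemble)
    if (!all(g$nodes %in% variables))
      stop("graph node not among the supplied variables")
  if (length(variables) < 2L) stop("need at least two variables")

  pairs <- t(utils::combn(sort(variables), 2L))
  key <- paste(pairs[, 1], pairs[, 2], sep = "\r")
  left <- none <- right <- integer(nrow(pairs))
  for (g in ensemble) {
    e <- g$edges
    if (nrow(e)) {
      fwd <- e[, 1] < e[, 2]
      kright <- paste(e[fwd, 1], e[fwd, 2], sep = "\r")
      kleft <- paste(e[!fwd, 2], e[!fwd, 1], sep = "\r")
      if (anyDuplicated(c(kright, kleft)))
        stop("graph contains both directions of an edge; not an acyclic graph")
      right <- right + (key %in% kright)
      left <- left + (key %in% kleft)
    }
  }
  k <- length(ensemble)
  none <- k - left - right
  out <- data.frame(from = pairs[, 1], to = pairs[, 2],
                    left = as.integer(left), none = as.integer(none),
                    right = as.integer(right), stringsAsFactors = FALSE)
  structure(out, k = k, class = c("edge_census", "data.frame"))
}

#' Combine censuses of two ensembles
#'
#' Element-wise sum of the counts; equals the census of the concatenated
#' ensembles.
#'
#' @param a,b `edge_census` objects over the same variable pairs.
#' @return an `edge_census` with counts summed and `k = k_a + k_b`.
#' @export
combine_censuses <- function(a, b) {
  stopifnot(inherits(a, "edge_census"), inherits(b, "edge_census"))
  if (!identical(a$from, b$from) || !identical(a$to, b$to))
    stop("censuses cover different variable pairs")
  out <- a
  for (col in c("left", "none", "right")) out[[col]] <- a[[col]] + b[[col]]
  attr(out, "k") <- attr(a, "k") + attr(b, "k")
  out
}
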