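#' Score-based structure learning by hill climbing
#'
#' Greedy local search over DAGs under a decomposable score ([bic_score()] or
#' [bdeu_score()]). Starting from the empty graph, every single-edge move
#' (delete, reverse, add) is evaluated and the best-improving one is applied
#' until no move improves the score. Because the downstream ensemble
#' statistics depend on which local optimum is returned, the search is fully
#' deterministic: moves are scanned in a fixed order (deletions before
#' reversals before additions, then lexicographic on parent then child) and
#' exact score ties go to the earliest move in that order. `restarts > 0` adds
#' seeded random restarts that permute the scan order; the best-scoring final
#' graph wins.
#'
#' @param D a [tab_data] (or coercible) with at least one row.
#' @param cfg a [score_config]; default BDeu with `ess = 1`.
#' @param seed integer seed controlling restart permutations (unused when
#'   `restarts = 0`).
#' @param restarts number of additional randomly-permuted searches.
#' @param max_iter cap on accepted moves per search.
#' @return a [dag] that is a local optimum: no single edge addition, deletion
#'   or reversal improves its score.
#' @export
hill_climb <- function(D, cfg = score_config(), seed = 1L, restarts = 0L,
                       max_iter = 200L) {
  D <- as_tab_data(D)
  if (D$n_rows < 1L) stop("cannot learn from an empty dataset")
  stopifnot(inherits(cfg, "score_config"))
  fs <- make_family_scorer(D, cfg)
  vars <- D$variables

  base <- hc_search(vars, fs, cfg, max_iter, perm = NULL)
  if (restarts > 0L) {
    rseeds <- derive_seeds(seed, restarts)
    for (r in seq_len(restarts)) {
      cand <- hc_search(vars, fs, cfg, max_iter,
                        perm = with_seed(rseeds[r], sample(length(vars))))
      if (cand$score > base$score + 1e-9) base <- cand
    }
  }
  pa <- base$pa
  edges <- do.call(rbind, lapply(names(pa), function(v) {
    if (length(pa[[v]])) cbind(pa[[v]], v) else NULL
  }))
  dag(vars, edges)
}

# One greedy search. State is the list of parent sets `pa`. `perm` permutes
# the node order used to enumerate moves (NULL = natural lexicographic).
hc_search <- function(vars, fs, cfg, max_iter, perm = NULL) {
  ord <- if (is.null(perm)) sort(vars) else sort(vars)[perm]
  pa <- stats::setNames(vector("list", length(vars)), vars)
  for (v in vars) pa[[v]] <- character(0)
  fam <- vapply(vars, function(v) fs(v, pa[[v]]), 0)

  reachable <- function(from, to) { # path from -> to under current pa?
    stack <- from
    seen <- character(0)
    while (length(stack)) {
      v <- stack[[length(stack)]]; stack <- stack[-length(stack)]
      if (v == to) return(TRUE)
      if (v %in% seen) next
      seen <- c(seen, v)
      ch <- vars[vapply(vars, function(w) v %in% pa[[w]], NA)]
      stack <- c(stack, ch)
    }
    FALSE
  }

  for (iter in seq_len(max_iter)) {
    best <- list(delta = 1e-10, move = NULL)
    for (u in ord) for (v in ord) {
      if (u == v) next
      if (u %in% pa[[v]]) {
        # delete u -> v
        d <- fs(v, setdiff(pa[[v]], u)) - fam[[v]]
        if (d > best$delta) best <- list(delta = d, move = c("delete", u, v))
      }
    }
    for (u in ord) for (v in ord) {
      if (u == v || !(u %in% pa[[v]])) next
      # reverse u -> v: drop it, add v -> u (only if still acyclic)
      if (length(pa[[u]]) + 1L > cfg$max_parents) next
      pa_v_old <- pa[[v]]
      pa[[v]] <- setdiff(pa_v_old, u)
      ok <- !reachable(u, v)
      d <- if (ok)
        (fs(v, pa[[v]]) - fam[[v]]) + (fs(u, c(pa[[u]], v)) - fam[[u]])
      else -Inf
      pa[[v]] <- pa_v_old
      if (ok && d > best$delta) best <- list(delta = d, move = c("reverse", u, v))
    }
    for (u in ord) for (v in ord) {
      if (u == v || u %in% pa[[v]] || v %in% pa[[u]]) next
      if (length(pa[[v]]) + 1L > cfg$max_parents) next
      if (reachable(v, u)) next   # u -> v would close a cycle
      d <- fs(v, c(pa[[v]], u)) - fam[[v]]
      if (d > best$delta) best <- list(delta = d, move = c("add", u, v))
    }
    if (is.null(best$move)) break
    m <- best$move
    u <- m[2]; v <- m[3]
    if (m[1] == "delete") {
      pa[[v]] <- setdiff(pa[[v]], u)
      fam[[v]] <- fs(v, pa[[v]])
    } else if (m[1] == "add") {
      pa[[v]] <- sort(c(pa[[v]], u))
      fam[[v]] <- fs(v, pa[[v]])
    } else {
      pa[[v]] <- setdiff(pa[[v]], u)
      pa[[u]] <- sort(c(pa[[u]], v))
      fam[[v]] <- fs(v, pa[[v]])
      fam[[u]] <- fs(u, pa[[u]])
    }
  }
  list(pa = pa, score = sum(fam))
}

#' Learn an ensemble of networks from bootstrap subsets
#'
#' Applies a structure learner to each subset produced by
#' [bootstrap_subsets()]. The learner is pluggable: any function mapping a
#' [tab_data] to a [dag] may stand in for the default hill climber, so
#' externally learned ensembles can feed the edge census.
#'
#' @param subsets list of [tab_data] objects.
#' @param learner function `tab_data -> dag`; default [hill_climb()] with
#'   `cfg`.
#' @param cfg a [score_config] used by the default learner.
#' @return list of [dag] objects, one per subset.
#' @export
learn_ensemble <- function(subsets, learner = NULL, cfg = score_config()) {
  if (is.null(learner)) learner <- function(d) hill_climb(d, cfg)
  lapply(subsets, function(d) {
    g <- learner(d)
    if (!inherits(g, "dag")) stop("learner must return a dag")
    g
  })
}
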