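# Independent oracles used across the suite. These deliberately avoid the
# package's own computation paths: the joint distribution is enumerated row
# by row, and DAG search is checked against exhaustive enumeration.

# Exact conditional P(target | evidence) by full-joint enumeration.
enumerate_conditional <- function(model, target, evidence = NULL) {
  vars <- model$graph$nodes
  grid <- expand.grid(model$categories[vars], stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  colnames(grid) <- vars
  jp <- rep(1, nrow(grid))
  for (v in vars) {
    pa <- parents(model$graph, v)
    cpt <- model$cpts[[v]]
    idx <- cbind(match(grid[[v]], model$categories[[v]]))
    for (p in pa) idx <- cbind(idx, match(grid[[p]], model$categories[[p]]))
    jp <- jp * cpt[idx]
  }
  keep <- rep(TRUE, nrow(grid))
  ev <- unlist(evidence)
  for (v in names(ev)) keep <- keep & grid[[v]] == ev[[v]]
  num <- tapply(jp[keep], factor(grid[[target]][keep],
                                 levels = model$categories[[target]]), sum)
  num[is.na(num)] <- 0
  as.numeric(num) / sum(num)
}

# All DAGs on the given (<= 3) labelled nodes, as edge matrices.
all_dags <- function(nodes) {
  pairs <- t(utils::combn(nodes, 2))
  arcs <- rbind(pairs, pairs[, 2:1, drop = FALSE])
  out <- list()
  for (mask in 0:(2^nrow(arcs) - 1)) {
    sel <- which(bitwAnd(mask, 2^(seq_len(nrow(arcs)) - 1)) > 0)
    e <- arcs[sel, , drop = FALSE]
    g <- tryCatch(dag(nodes, e), error = function(err) NULL)
    if (!is.null(g)) out[[length(out) + 1]] <- g
  }
  out
}

# TRUE if no single add/delete/reverse move improves the score of `g`.
is_local_optimum <- function(g, D, score_fun, tol = 1e-9) {
  s0 <- score_fun(g)
  nodes <- g$nodes
  for (u in nodes) for (v in nodes) {
    if (u == v) next
    if (has <- any(g$edges[, 1] == u & g$edges[, 2] == v)) {
      rest <- g$edges[!(g$edges[, 1] == u & g$edges[, 2] == v), , drop = FALSE]
      if (score_fun(dag(nodes, rest)) > s0 + tol) return(FALSE)
      rev_g <- tryCatch(dag(nodes, rbind(rest, c(v, u))),
                        error = function(e) NULL)
      if (!is.null(rev_g) && score_fun(rev_g) > s0 + tol) return(FALSE)
    } else if (!any(g$edges[, 1] == v & g$edges[, 2] == u)) {
      add_g <- tryCatch(dag(nodes, rbind(g$edges, c(u, v))),
                        error = function(e) NULL)
      if (!is.null(add_g) && score_fun(add_g) > s0 + tol) return(FALSE)
    }
  }
  TRUE
}

# Binary dataset with declared categories {0,1} from 0/1 vectors.
binary_data <- function(...) {
  cols <- list(...)
  codes <- do.call(cbind, lapply(cols, function(x) as.integer(x) + 1L))
  tab_data(codes, names(cols),
           stats::setNames(rep(list(c("0", "1")), length(cols)), names(cols)))
}

# Quick DAG over binary variables with a trivial uniform CPT set.
uniform_bn <- function(nodes, edges = NULL) {
  g <- dag(nodes, edges)
  cpts <- lapply(nodes, function(v) {
    pa <- parents(g, v)
    dims <- rep(2L, 1 + length(pa))
    dn <- rep(list(c("0", "1")), 1 + length(pa))
    names(dn) <- c(v, pa)
    array(0.5, dim = dims, dimnames = dn)
  })
  names(cpts) <- nodes
  discrete_bn(g, cpts)
}

canonical_pairs <- function(edges) {
  unique(t(apply(edges, 1, sort)))
}
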