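#' Discrete Bayesian network with conditional probability tables
#'
#' A [dag] plus one CPT per node. A node's CPT is an array whose first
#' dimension ranges over the node's categories and whose remaining dimensions
#' range over the categories of its parents in sorted order (the order
#' returned by [parents()]); `dimnames` carry the category labels and the
#' names of `dimnames` carry the variable names. Every parent-configuration
#' column must sum to 1. The joint distribution is the product of all CPT
#' entries, one factor per node given its parents.
#'
#' @param graph a [dag].
#' @param cpts named list of CPT arrays, one per node.
#' @return an object of class `discrete_bn` with fields `graph`, `cpts` and
#'   `categories` (named list of per-variable labels).
#' @export
discrete_bn <- function(graph, cpts) {
  stopifnot(inherits(graph, "dag"))
  if (!setequal(names(cpts), graph$nodes))
    stop("cpts must be a named list with one entry per node")
  cats <- list()
  for (v in graph$nodes) {
    cpt <- as_cpt_array(cpts[[v]], v)
    dn <- dimnames(cpt)
    cats[[v]] <- dn[[1L]]
    cpts[[v]] <- cpt
  }
  for (v in graph$nodes) {
    cpt <- cpts[[v]]
    pa <- parents(graph, v)
    want <- c(v, pa)
    if (!identical(names(dimnames(cpt)), want))
      stop("CPT of '", v, "' must be indexed by (", paste(want, collapse = ", "),
           ")")
    for (p in pa)
      if (!identical(dimnames(cpt)[[p]], cats[[p]]))
        stop("CPT of '", v, "' disagrees with categories of parent '", p, "'")
    sums <- if (length(pa) == 0L) sum(cpt)
            else apply(cpt, seq_along(dim(cpt))[-1L], sum)
    if (any(abs(sums - 1) > 1e-9))
      stop("CPT rows of '", v, "' must each sum to 1")
    if (any(cpt < 0)) stop("CPT of '", v, "' has negative probabilities")
  }
  structure(list(graph = graph, cpts = cpts, categories = cats[graph$nodes]),
            class = "discrete_bn")
}

# Coerce a vector (parentless node) or array to a dimnamed CPT array.
as_cpt_array <- function(x, node) {
  if (is.null(dim(x))) {
    labs <- names(x)
    if (is.null(labs)) labs <- as.character(seq_along(x) - 1L)
    x <- array(as.numeric(x), dim = length(x),
               dimnames = stats::setNames(list(labs), node))
  }
  if (is.null(dimnames(x)) || is.null(names(dimnames(x))))
    stop("CPT of '", node, "' needs named dimnames")
  x
}

#' @export
print.discrete_bn <- function(x, ...) {
  cat("Discrete Bayesian network:", length(x$graph$nodes), "nodes,",
      nrow(x$graph$edges), "edges\n")
  print(x$graph)
  invisible(x)
}

#' Ancestral (forward) sampling from a discrete network
#'
#' Draws `n` joint observations by sampling each node from its CPT row given
#' its already-sampled parents, in topological order. This is the package's
#' synthetic-data generator; the fixtures in [fixture_five_node()] and
#' [fixture_lucas()] are sampled this way.
#'
#' @param model a [discrete_bn].
#' @param n number of rows.
#' @param seed integer seed; output is deterministic given it.
#' @return a [tab_data] with the model's variables and categories.
#' @export
forward_sample <- function(model, n, seed = 1L) {
  stopifnot(inherits(model, "discrete_bn"))
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be >= 1")
  vars <- model$graph$nodes
  codes <- matrix(0L, n, length(vars), dimnames = list(NULL, vars))
  with_seed(seed, for (v in topological_order(model$graph)) {
    cpt <- model$cpts[[v]]
    pa <- parents(model$graph, v)
    r <- length(model$categories[[v]])
    if (length(pa) == 0L) {
      cfg <- rep.int(1L, n)
      q <- 1L
    } else {
      cfg <- rep.int(0L, n); q <- 1L
      for (p in pa) {
        cfg <- cfg + (codes[, p] - 1L) * q
        q <- q * length(model$categories[[p]])
      }
      cfg <- cfg + 1L
    }
    pm <- matrix(cpt, nrow = r)            # r x q, column-major over parents
    cs <- apply(pm[, cfg, drop = FALSE], 2, cumsum)
    if (r == 1L) cs <- matrix(cs, nrow = 1L)
    u <- stats::runif(n)
    codes[, v] <- 1L + colSums(cs < rep(u, each = r) - 1e-15)
  })
  tab_data(codes, vars, model$categories)
}

#' Fit CPTs for a fixed structure
#'
#' Maximum-likelihood or additively smoothed CPT estimates: each entry is
#' `(count + smoothing) / (config_total + smoothing * arity)`. With
#' `smoothing = 0` an unobserved parent configuration leaves a CPT row
#' undefined and is an error.
#'
#' @param graph a [dag].
#' @param D a [tab_data] (or coercible) containing every node of `graph`.
#' @param smoothing non-negative pseudo-count per CPT cell (0 = maximum
#'   likelihood).
#' @return a [discrete_bn].
#' @export
fit_cpts <- function(graph, D, smoothing = 0) {
  stopifnot(inherits(graph, "dag"))
  D <- as_tab_data(D)
  if (!all(graph$nodes %in% D$variables))
    stop("graph node not present in dataset")
  if (smoothing < 0) stop("smoothing must be >= 0")
  cpts <- list()
  for (v in graph$nodes) {
    pa <- parents(graph, v)
    counts <- family_counts(D, v, pa)       # r x q
    r <- nrow(counts)
    totals <- colSums(counts)
    if (smoothing == 0 && any(totals == 0))
      stop("unobserved parent configuration for '", v,
           "' with smoothing = 0; CPT row undefined")
    probs <- sweep(counts + smoothing, 2, totals + smoothing * r, "/")
    dims <- unname(c(r, vapply(pa, function(p) length(D$categories[[p]]), 0L)))
    dn <- c(list(D$categories[[v]]),
            lapply(pa, function(p) D$categories[[p]]))
    names(dn) <- c(v, pa)
    cpts[[v]] <- array(probs, dim = dims, dimnames = dn)
  }
  discrete_bn(graph, cpts)
}

#' Sample size needed to observe a rare event
#'
#' How many i.i.d. samples are required for an event of probability
#' `p_event` to appear at least once with the requested confidence. The rule
#' of three is the classic 95% approximation `ceiling(3 / p)`; `"exact"`
#' inverts the complement, `ceiling(log(1 - confidence) / log(1 - p))`, and
#' returns 1 when `p_event = 1`.
#'
#' @param p_event event probability in (0, 1].
#' @param confidence target probability of at least one occurrence (used by
#'   the exact method; the rule of three is calibrated to 0.95).
#' @param method `"rule_of_three"` or `"exact"`.
#' @return integer sample count.
#' @export
required_sample_size <- function(p_event, confidence = 0.95,
                                 method = c("rule_of_three", "exact")) {
  method <- match.arg(method)
  if (!is.numeric(p_event) || p_event <= 0 || p_event > 1)
    stop("p_event must be in (0, 1]")
  if (confidence <= 0 || confidence >= 1) stop("confidence must be in (0, 1)")
  if (method == "rule_of_three") return(as.integer(ceiling(3 / p_event)))
  if (p_event == 1) return(1L)
  as.integer(ceiling(log(1 - confidence) / log(1 - p_event)))
}
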