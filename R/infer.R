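#' Exact inference by variable elimination
#'
#' Computes the conditional distribution of `target` given a (possibly
#' empty) evidence assignment, by sum-product variable elimination over the
#' CPT factors. On the network sizes this package targets the computation is
#' exact; evidence with zero probability under the model is an error.
#'
#' @param model a [discrete_bn].
#' @param target variable name, not part of the evidence.
#' @param evidence named character vector or list mapping variables to
#'   observed category labels.
#' @return named probability vector over the target's categories.
#' @export
infer <- function(model, target, evidence = NULL) {
  stopifnot(inherits(model, "discrete_bn"))
  vars <- model$graph$nodes
  if (!target %in% vars) stop("unknown target '", target, "'")
  ev <- unlist(evidence)
  if (length(ev)) {
    if (is.null(names(ev)) || any(!nzchar(names(ev))))
      stop("evidence must be named")
    if (target %in% names(ev)) stop("target cannot be part of the evidence")
    if (!all(names(ev) %in% vars)) stop("unknown evidence variable")
    for (v in names(ev))
      if (!ev[[v]] %in% model$categories[[v]])
        stop("unknown category '", ev[[v]], "' for variable '", v, "'")
  }
  arity <- vapply(model$categories, length, 0L)

  factors <- lapply(vars, function(v)
    reduce_factor(list(vars = c(v, parents(model$graph, v)),
                       tab = model$cpts[[v]]), ev))
  hidden <- sort(setdiff(vars, c(target, names(ev))))
  for (h in hidden) {
    inv <- vapply(factors, function(f) h %in% f$vars, NA)
    if (!any(inv)) next
    prod <- Reduce(function(a, b) mult_factor(a, b, arity), factors[inv])
    factors <- c(factors[!inv], list(marg_factor(prod, h)))
  }
  res <- Reduce(function(a, b) mult_factor(a, b, arity), factors)
  out <- as.numeric(res$tab)
  if (length(res$vars) != 1L || res$vars != target) {
    # only scalars besides the target factor remain; collapse them
    stop("internal error: elimination left variables ",
         paste(res$vars, collapse = ", "))
  }
  z <- sum(out)
  if (z <= 0) stop("impossible evidence: observed assignment has probability 0")
  stats::setNames(out / z, model$categories[[target]])
}

# Slice evidence variables out of a factor.
reduce_factor <- function(f, ev) {
  common <- intersect(f$vars, names(ev))
  if (!length(common)) return(f)
  idx <- rep(list(quote(expr = )), length(f$vars))
  for (v in common)
    idx[[match(v, f$vars)]] <- match(ev[[v]], dimnames(f$tab)[[v]])
  tab <- do.call(`[`, c(list(f$tab), idx, list(drop = FALSE)))
  keep <- setdiff(f$vars, common)
  if (!length(keep)) return(list(vars = character(0), tab = sum(tab)))
  d <- dim(tab)[match(keep, f$vars)]
  dn <- dimnames(f$tab)[keep]
  list(vars = keep, tab = array(as.vector(tab), dim = d, dimnames = dn))
}

mult_factor <- function(f1, f2, arity) {
  if (!length(f1$vars))
    return(list(vars = f2$vars, tab = f2$tab * as.numeric(f1$tab)))
  if (!length(f2$vars))
    return(list(vars = f1$vars, tab = f1$tab * as.numeric(f2$tab)))
  all_vars <- union(f1$vars, f2$vars)
  list(vars = all_vars,
       tab = expand_factor(f1, all_vars, arity) *
         expand_factor(f2, all_vars, arity))
}

# Broadcast a factor to the full variable set `all_vars` (in that order).
expand_factor <- function(f, all_vars, arity) {
  miss <- setdiff(all_vars, f$vars)
  tab <- f$tab
  if (length(miss)) {
    tab <- array(rep(as.vector(tab), prod(arity[miss])),
                 dim = c(dim(f$tab), arity[miss]))
  }
  aperm(array(tab, dim = dim(tab)), match(all_vars, c(f$vars, miss)))
}

marg_factor <- function(f, var) {
  i <- match(var, f$vars)
  keep <- seq_along(f$vars)[-i]
  if (!length(keep)) return(list(vars = character(0), tab = sum(f$tab)))
  dn <- if (!is.null(dimnames(f$tab))) dimnames(f$tab)[keep] else NULL
  tab <- apply(f$tab, keep, sum)
  list(vars = f$vars[keep],
       tab = array(tab, dim = dim(f$tab)[keep], dimnames = dn))
}

#' Confusion counts for target prediction
#'
#' Prediction protocol for evaluating a learned network on held-out data:
#' for every test row, the target's conditional distribution given all
#' remaining variables is computed with [infer()] and the arg-max category is
#' predicted (ties to the lexicographically first category). The target must
#' be binary; its lexicographically larger category is treated as the
#' positive class. Rates are fractions of the test-set size, so the four sum
#' to 1.
#'
#' @param model a [discrete_bn].
#' @param test a [tab_data] (or coercible) with the model's variables; its
#'   category labels must be a subset of the model's.
#' @param target name of a binary variable.
#' @return object of class `confusion_counts`: list with integer `tp`, `tn`,
#'   `fp`, `fn`, `total`, and `rates` (named numeric, fractions of total).
#' @export
evaluate_inference <- function(model, test, target) {
  stopifnot(inherits(model, "discrete_bn"))
  test <- as_tab_data(test)
  cats <- model$categories[[target]]
  if (is.null(cats)) stop("unknown target '", target, "'")
  if (length(cats) != 2L) stop("target must be binary")
  pos <- cats[2L]                     # lexicographically larger category
  others <- setdiff(test$variables, target)
  others <- intersect(others, model$graph$nodes)
  df <- as.data.frame(test)
  tp <- tn <- fp <- fn <- 0L
  cache <- new.env(parent = emptyenv())
  for (i in seq_len(test$n_rows)) {
    ev <- stats::setNames(as.character(df[i, others]), others)
    key <- paste(ev, collapse = "\r")
    pred <- cache[[key]]
    if (is.null(pred)) {
      p <- infer(model, target, ev)
      pred <- names(p)[which.max(p)]   # which.max: first index on ties
      cache[[key]] <- pred
    }
    truth <- df[i, target]
    if (truth == pos) {
      if (pred == pos) tp <- tp + 1L else fn <- fn + 1L
    } else {
      if (pred == pos) fp <- fp + 1L else tn <- tn + 1L
    }
  }
  total <- test$n_rows
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn, total = total,
                 rates = c(tp = tp, tn = tn, fp = fp, fn = fn) / total),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat("Confusion counts over", x$total, "test rows\n")
  print(round(100 * x$rates, 1))
  invisible(x)
}
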