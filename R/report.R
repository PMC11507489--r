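#' Edge credibility analysis of a dataset
#'
#' The full pipeline: bootstrap the dataset into `k` subsets of `n` rows,
#' learn one network per subset, take the edge-state census over the
#' ensemble, and fit a Dirichlet-Multinomial posterior to every variable
#' pair, with existence/direction summaries and the MAP state per pair.
#'
#' @param D a [tab_data] or coercible data.frame.
#' @param k number of bootstrap subsets.
#' @param n rows per subset (`NULL` = as many as `D` has).
#' @param seed master seed for resampling (and the sampler when
#'   `engine = "mcmc"`).
#' @param cfg [score_config] for the default hill-climbing learner.
#' @param learner optional replacement learner, a function
#'   `tab_data -> dag`.
#' @param prior Dirichlet prior over the three edge states.
#' @param level credible level for all intervals.
#' @param engine `"analytic"` (conjugate closed form, default) or `"mcmc"`
#'   (Metropolis sampling via [mcmc_posterior()]).
#' @param draws retained MCMC draws per chain when `engine = "mcmc"`.
#' @return an object of class `credibility_report`: fields `variables`,
#'   `census`, `pairs` (per pair: `posterior`, `summary`, `map`), and `meta`
#'   (k, n, seed, learner settings, prior, level, engine).
#' @examples
#' bn <- fixture_five_node()
#' D <- forward_sample(bn, 400, seed = 7)
#' rep <- edge_credibility(D, k = 20, n = 100, seed = 7)
#' head(as.data.frame(rep))
#' @export
edge_credibility <- function(D, k = 100L, n = NULL, seed = 1L,
                             cfg = score_config(), learner = NULL,
                             prior = rep(1 / 3, 3), level = 0.95,
                             engine = c("analytic", "mcmc"), draws = 2000L) {
  engine <- match.arg(engine)
  D <- as_tab_data(D)
  subsets <- bootstrap_subsets(D, resample_plan(k = k, n = n, seed = seed))
  ensemble <- learn_ensemble(subsets, learner = learner, cfg = cfg)
  census <- count_edge_states(ensemble, D$variables)
  report_from_census(census, prior = prior, level = level, engine = engine,
                     draws = draws, seed = seed,
                     meta = list(k = as.integer(k),
                                 n = if (is.null(n)) D$n_rows else as.integer(n),
                                 seed = as.integer(seed),
                                 score = cfg$score, ess = cfg$ess,
                                 custom_learner = !is.null(learner)))
}

#' Credibility report from a precomputed census
#'
#' Lower-level entry point: builds the per-pair posteriors and summaries from
#' an [count_edge_states()] census, for ensembles learned elsewhere.
#'
#' @param census an `edge_census`.
#' @inheritParams edge_credibility
#' @param meta list of provenance fields stored in the report.
#' @return a `credibility_report`.
#' @export
report_from_census <- function(census, prior = rep(1 / 3, 3), level = 0.95,
                               engine = c("analytic", "mcmc"), draws = 2000L,
                               seed = 1L, meta = list()) {
  engine <- match.arg(engine)
  stopifnot(inherits(census, "edge_census"))
  pair_seeds <- derive_seeds(seed, nrow(census))
  pairs <- lapply(seq_len(nrow(census)), function(i) {
    row <- census[i, ]
    post <- if (engine == "analytic")
      posterior_from_counts(row, prior = prior, level = level)
    else
      mcmc_posterior(row, prior = prior, level = level, draws = draws,
                     seed = pair_seeds[i])
    list(posterior = post, summary = existence_direction(post),
         map = map_state(post))
  })
  vars <- sort(unique(c(census$from, census$to)))
  meta <- utils::modifyList(
    list(k = attr(census, "k"), prior = prior, level = level,
         engine = engine), meta)
  structure(list(variables = vars, census = census, pairs = pairs,
                 meta = meta),
            class = "credibility_report")
}

#' @export
print.credibility_report <- function(x, ...) {
  cat("Edge credibility report:", length(x$variables), "variables,",
      length(x$pairs), "pairs, ensemble size", x$meta$k, "\n")
  df <- as.data.frame(x)
  show <- df[order(-df$exists_mean), ]
  cat("Top pairs by existence probability:\n")
  print(utils::head(show[, c("from", "to", "left", "none", "right",
                             "exists_mean", "map")], 8), row.names = FALSE)
  invisible(x)
}

#' Flatten a credibility report to a data frame
#'
#' One row per variable pair with counts, posterior means, per-state interval
#' bounds, MAP state, and the existence/direction summaries. Suitable for
#' CSV export.
#'
#' @param x a `credibility_report`.
#' @param ... unused.
#' @return data.frame with `choose(n_vars, 2)` rows.
#' @export
as.data.frame.credibility_report <- function(x, ...) {
  rows <- lapply(x$pairs, function(p) {
    po <- p$posterior; s <- p$summary
    data.frame(
      from = po$pair[1], to = po$pair[2],
      left = po$counts[["left"]], none = po$counts[["none"]],
      right = po$counts[["right"]],
      mean_left = po$mean[["left"]], mean_none = po$mean[["none"]],
      mean_right = po$mean[["right"]],
      low_left = po$interval["left", "low"], high_left = po$interval["left", "high"],
      low_none = po$interval["none", "low"], high_none = po$interval["none", "high"],
      low_right = po$interval["right", "low"], high_right = po$interval["right", "high"],
      exists_mean = s$exists_mean,
      exists_low = s$exists_interval[1], exists_high = s$exists_interval[2],
      direction_mean = s$direction_mean,
      direction_low = s$direction_interval[1],
      direction_high = s$direction_interval[2],
      map = p$map, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a credibility report to JSON
#'
#' Machine-readable serialization: a `meta` object (k, n, seed, learner
#' settings, prior, level, engine) and a `pairs` array with one record per
#' variable pair carrying counts, posterior means, intervals, MAP state and
#' the existence/direction summaries. MCMC draws are not serialized.
#'
#' @param report a `credibility_report`.
#' @param path output file path.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "credibility_report"))
  pairs <- lapply(report$pairs, function(p) {
    po <- p$posterior; s <- p$summary
    list(from = po$pair[1], to = po$pair[2],
         counts = as.list(po$counts),
         alpha = as.list(po$alpha),
         mean = as.list(po$mean),
         interval = list(left = unname(po$interval["left", ]),
                         none = unname(po$interval["none", ]),
                         right = unname(po$interval["right", ])),
         map = p$map,
         exists = list(mean = s$exists_mean,
                       interval = unname(s$exists_interval)),
         direction = list(mean = s$direction_mean,
                          interval = unname(s$direction_interval)))
  })
  jsonlite::write_json(
    list(meta = report$meta, variables = report$variables, pairs = pairs),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write a directed graph to DOT or GraphML
#'
#' Exports a learned or MAP graph for standard graph tools. All nodes are
#' written, including isolated ones. Optional per-edge attributes `weight`
#' (posterior mean of the drawn direction) and `frequency` (ensemble
#' occurrence fraction) are attached when supplied; both drive the edge-width
#' rendering conventions of downstream viewers.
#'
#' @param graph a [dag] or [digraph].
#' @param path output file path.
#' @param format `"dot"` or `"graphml"`.
#' @param weight,frequency optional numeric vectors, one entry per edge (in
#'   `graph$edges` row order).
#' @export
write_graph_file <- function(graph, path, format = c("dot", "graphml"),
                             weight = NULL, frequency = NULL) {
  format <- match.arg(format)
  if (!inherits(graph, "dag") && !inherits(graph, "digraph"))
    stop("graph must be a dag or digraph")
  ig <- igraph::make_empty_graph(directed = TRUE) +
    igraph::vertices(graph$nodes)
  if (nrow(graph$edges))
    ig <- ig + igraph::edges(t(graph$edges))
  if (!is.null(weight)) {
    if (length(weight) != nrow(graph$edges))
      stop("one weight per edge required")
    igraph::E(ig)$weight <- weight
  }
  if (!is.null(frequency)) {
    if (length(frequency) != nrow(graph$edges))
      stop("one frequency per edge required")
    igraph::E(ig)$frequency <- frequency
  }
  igraph::V(ig)$name <- graph$nodes
  tryCatch(igraph::write_graph(ig, path, format = format),
           error = function(e) stop("cannot write graph to ", path, ": ",
                                    conditionMessage(e)))
  invisible(path)
}

#' MAP graph with edge attributes, written in one call
#'
#' Convenience wrapper: builds the thresholded MAP graph of a report and
#' writes it with `weight` (posterior mean of the emitted direction) and
#' `frequency` (ensemble fraction of that direction) per edge.
#'
#' @inheritParams map_graph
#' @inheritParams write_graph_file
#' @return the [digraph], invisibly.
#' @export
write_map_graph <- function(report, path, threshold = 0.75,
                            format = c("dot", "graphml")) {
  g <- map_graph(report, threshold)
  w <- f <- numeric(nrow(g$edges))
  if (nrow(g$edges)) {
    lut <- stats::setNames(report$pairs,
                           paste(report$census$from, report$census$to,
                                 sep = "\r"))
    for (i in seq_len(nrow(g$edges))) {
      a <- g$edges[i, 1]; b <- g$edges[i, 2]
      canon <- sort(c(a, b))
      p <- lut[[paste(canon[1], canon[2], sep = "\r")]]
      state <- if (a == canon[1]) "right" else "left"
      w[i] <- p$posterior$mean[[state]]
      f[i] <- p$posterior$counts[[state]] / attr(report$census, "k")
    }
  }
  write_graph_file(g, path, format = format, weight = w, frequency = f)
  invisible(g)
}
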