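#' Dirichlet-Multinomial posterior for the state of one edge
#'
#' Conjugate update for the three edge states (left, none, right) of a
#' variable pair: with prior `Dirichlet(prior)` and observed ensemble counts
#' `(left, none, right)`, the posterior is
#' `Dirichlet(prior + counts)`. The uninformative default prior is
#' `(1/3, 1/3, 1/3)`, one pseudo-observation split evenly over the states.
#'
#' @param counts integer vector `(left, none, right)`, or a single-row subset
#'   of an [count_edge_states()] census.
#' @param prior three positive reals, order left/none/right.
#' @param level credible level for the per-state equal-tailed intervals.
#' @param pair optional `c(from, to)` canonical pair labels.
#' @return an object of class `edge_posterior` with fields `pair`, `counts`,
#'   `alpha` (posterior Dirichlet parameters), `mean` (posterior means,
#'   summing to 1), `interval` (3 x 2 matrix of per-state equal-tailed
#'   Beta-marginal bounds), `level`, and `draws` (`NULL` for the analytic
#'   path).
#' @export
posterior_from_counts <- function(counts, prior = rep(1 / 3, 3),
                                  level = 0.95, pair = NULL) {
  cx <- as_state_counts(counts)
  if (is.null(pair)) pair <- cx$pair
  counts <- cx$counts
  if (length(prior) != 3L || any(!is.finite(prior)) || any(prior <= 0))
    stop("prior must be three positive reals")
  if (any(counts < 0)) stop("counts must be non-negative")
  alpha <- prior + counts
  post <- structure(
    list(pair = pair, counts = counts, alpha = stats::setNames(
      alpha, c("left", "none", "right")),
      mean = stats::setNames(alpha / sum(alpha), c("left", "none", "right")),
      draws = NULL, level = level, interval = NULL),
    class = "edge_posterior")
  post$interval <- credible_interval(post, level)
  post
}

# Accept a bare 3-vector or one census row; returns counts + pair labels.
as_state_counts <- function(x) {
  if (is.data.frame(x)) {
    if (nrow(x) != 1L) stop("expected a single census row")
    list(counts = c(left = x$left, none = x$none, right = x$right),
         pair = c(x$from, x$to))
  } else {
    x <- as.numeric(x)
    if (length(x) != 3L) stop("counts must be (left, none, right)")
    list(counts = stats::setNames(x, c("left", "none", "right")), pair = NULL)
  }
}

#' Equal-tailed credible intervals for each edge state
#'
#' For an analytic posterior, each state's marginal under
#' `Dirichlet(alpha)` is `Beta(alpha_i, sum(alpha) - alpha_i)` and the
#' interval is taken from its quantiles. For a sample-based posterior the
#' empirical quantiles of the draws are used. `type = "hpd"` gives the
#' highest-posterior-density interval instead (narrowest interval of the
#' requested mass).
#'
#' @param posterior an `edge_posterior`.
#' @param level interval mass, in (0, 1).
#' @param type `"equal_tailed"` (default) or `"hpd"`.
#' @return 3 x 2 matrix, rows left/none/right, columns `low`/`high`.
#' @export
credible_interval <- function(posterior, level = posterior$level,
                              type = c("equal_tailed", "hpd")) {
  type <- match.arg(type)
  if (!is.numeric(level) || level <= 0 || level >= 1)
    stop("level must be in (0, 1)")
  out <- matrix(NA_real_, 3, 2,
                dimnames = list(c("left", "none", "right"), c("low", "high")))
  if (!is.null(posterior$draws)) {
    for (i in 1:3) {
      x <- posterior$draws[, i]
      out[i, ] <- if (type == "equal_tailed")
        unname(stats::quantile(x, c((1 - level) / 2, (1 + level) / 2)))
      else hpd_from_draws(x, level)
    }
    return(out)
  }
  alpha <- posterior$alpha
  a0 <- sum(alpha)
  for (i in 1:3) {
    a <- alpha[i]; b <- a0 - alpha[i]
    out[i, ] <- if (type == "equal_tailed")
      stats::qbeta(c((1 - level) / 2, (1 + level) / 2), a, b)
    else hpd_beta(a, b, level)
  }
  out
}

hpd_from_draws <- function(x, level) {
  x <- sort(x)
  n <- length(x)
  m <- max(1L, ceiling(level * n))
  if (m >= n) return(c(x[1L], x[n]))
  widths <- x[(m + 1L):n] - x[1:(n - m)]
  i <- which.min(widths)
  c(x[i], x[i + m])
}

# Narrowest interval of Beta(a, b) mass `level`, by optimising the lower tail.
hpd_beta <- function(a, b, level) {
  f <- function(p) stats::qbeta(p + level, a, b) - stats::qbeta(p, a, b)
  p <- stats::optimize(f, c(0, 1 - level))$minimum
  stats::qbeta(c(p, p + level), a, b)
}

#' MCMC posterior for the state of one edge
#'
#' Samples the Dirichlet-Multinomial edge posterior by Metropolis-within-
#' Gibbs on the gamma augmentation of the Dirichlet: with independent
#' `g_i ~ Gamma(alpha_i, 1)` the normalised vector `g / sum(g)` is
#' `Dirichlet(alpha)`, so the sampler random-walks each coordinate
#' `y_i = log(g_i)` against its 1-D target
#' `alpha_i * y - exp(y)` (log-gamma density including the Jacobian). The
#' three coordinates are updated in turn with per-coordinate step sizes that
#' adapt towards a 44% acceptance rate during burn-in and are then frozen;
#' several chains run side by side (vectorised). Convergence is checked with
#' the split-Rhat statistic over all chains and values above `rhat_max`
#' raise an error carrying the diagnostics. The analytic path
#' [posterior_from_counts()] is the conjugate oracle this sampler must agree
#' with; the sampler exists as the extension point for non-conjugate priors.
#'
#' @inheritParams posterior_from_counts
#' @param draws number of retained draws per chain (>= 1000).
#' @param seed integer seed; the sampler is deterministic given it.
#' @param burnin discarded adaptation iterations per chain.
#' @param chains number of parallel chains (>= 2 for the Rhat check).
#' @param rhat_max convergence threshold on split-Rhat (default 1.1).
#' @return an `edge_posterior` whose `draws` field holds the pooled
#'   `chains * draws` x 3 matrix of simplex points; `mean` and `interval`
#'   are computed from the draws.
#' @export
mcmc_posterior <- function(counts, prior = rep(1 / 3, 3), draws = 3000L,
                           seed = 1L, level = 0.95, burnin = 1000L,
                           chains = 8L, rhat_max = 1.1, pair = NULL) {
  if (draws < 1000L) stop("draws must be >= 1000")
  if (chains < 2L) stop("need at least two chains for the Rhat diagnostic")
  cx <- as_state_counts(counts)
  if (is.null(pair)) pair <- cx$pair
  alpha <- prior + cx$counts
  if (any(!is.finite(alpha)) || any(prior <= 0))
    stop("prior must be three positive reals")

  # state: 3 x chains matrix of y = log(gamma) coordinates
  sims <- lapply(seq_len(chains), function(i) matrix(NA_real_, draws, 3))
  with_seed(seed, {
  y <- matrix(log(stats::rgamma(3L * chains, shape = rep(alpha, chains))),
              nrow = 3L)
  step <- rep(1, 3L)
  acc <- rep(0, 3L)
  for (it in seq_len(burnin + draws)) {
    for (i in 1:3) {
      yp <- y[i, ] + step[i] * stats::rnorm(chains)
      logr <- alpha[i] * (yp - y[i, ]) - (exp(yp) - exp(y[i, ]))
      ok <- log(stats::runif(chains)) < logr
      y[i, ok] <- yp[ok]
      if (it <= burnin) acc[i] <- acc[i] + mean(ok)
    }
    if (it <= burnin && it %% 50L == 0L) {    # adapt towards 44% acceptance
      step <- step * exp(acc / 50 - 0.44)
      acc[] <- 0
    }
    if (it > burnin) {
      g <- exp(y)
      theta <- sweep(g, 2, colSums(g), "/")
      for (ch in seq_len(chains)) sims[[ch]][it - burnin, ] <- theta[, ch]
    }
  }
  })
  rhat <- vapply(1:3, function(i)
    split_rhat(vapply(sims, function(m) m[, i], numeric(draws))), 0)
  if (any(rhat > rhat_max))
    stop("MCMC did not converge: split-Rhat = (",
         paste(sprintf("%.3f", rhat), collapse = ", "),
         ") exceeds ", rhat_max)
  pooled <- do.call(rbind, sims)
  colnames(pooled) <- c("left", "none", "right")
  post <- structure(
    list(pair = pair, counts = cx$counts,
         alpha = stats::setNames(alpha, c("left", "none", "right")),
         mean = stats::setNames(colMeans(pooled), c("left", "none", "right")),
         draws = pooled, level = level, interval = NULL,
         diagnostics = list(rhat = rhat)),
    class = "edge_posterior")
  post$interval <- credible_interval(post, level)
  post
}

# Split-Rhat over a draws x chains matrix (each chain split in two halves).
split_rhat <- function(x) {
  n <- nrow(x)
  half <- floor(n / 2)
  halves <- cbind(x[seq_len(half), , drop = FALSE],
                  x[(n - half + 1):n, , drop = FALSE])
  m <- ncol(halves)
  means <- colMeans(halves)
  vars <- apply(halves, 2, stats::var)
  B <- half * stats::var(means)
  W <- mean(vars)
  if (W < 1e-300) return(1)
  sqrt(((half - 1) / half * W + B / half) / W)
}

#' @export
print.edge_posterior <- function(x, ...) {
  lab <- if (!is.null(x$pair)) paste(x$pair, collapse = " -- ") else "pair"
  cat("Edge-state posterior for ", lab,
      if (!is.null(x$draws)) "  (MCMC)" else "  (analytic)", "\n", sep = "")
  tab <- cbind(mean = x$mean, x$interval)
  print(round(tab, 4))
  invisible(x)
}
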