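test_that("conjugate update: posterior = prior + counts", {
  p0 <- posterior_from_counts(c(0, 0, 0))
  expect_equal(unname(p0$mean), rep(1 / 3, 3))

  p1 <- posterior_from_counts(c(0, 10, 0))
  expect_equal(p1$mean[["none"]], (10 + 1 / 3) / 11, tolerance = 1e-12)

  p2 <- posterior_from_counts(c(41, 38, 21))
  expect_equal(unname(p2$alpha), c(41, 38, 21) + 1 / 3)
  expect_equal(unname(p2$mean),
               (c(41, 38, 21) + 1 / 3) / 101, tolerance = 1e-12)
  # printed one-decimal percentages: 41% / 38% / 21%
  expect_equal(round(100 * unname(p2$mean)), c(41, 38, 21))
  expect_equal(sum(p2$mean), 1, tolerance = 1e-9)
  expect_error(posterior_from_counts(c(1, 1, 1), prior = c(0, 1, 1)),
               "positive")
})

test_that("credible intervals come from the Beta marginals", {
  p <- posterior_from_counts(c(41, 38, 21))
  ci <- credible_interval(p, 0.95)
  # left state ~ Beta(41.33, 59.67); frozen from qbeta
  expect_equal(unname(ci["left", ]), c(0.3157374, 0.5061503), tolerance = 1e-5)
  expect_true(all(ci[, "low"] <= p$mean & p$mean <= ci[, "high"]))

  conc <- posterior_from_counts(c(1e6, 1, 1) - 1 / 3)  # alpha ~ (1e6, 1, 1)
  w <- credible_interval(conc, 0.95)
  expect_lt(w["left", "high"] - w["left", "low"], 0.01)

  sym <- posterior_from_counts(c(12, 30, 12))
  cs <- credible_interval(sym, 0.9)
  expect_equal(cs["left", ], cs["right", ], ignore_attr = TRUE)

  hpd <- credible_interval(p, 0.95, type = "hpd")
  expect_lte(hpd["left", "high"] - hpd["left", "low"],
             ci["left", "high"] - ci["left", "low"] + 1e-9)
  expect_error(credible_interval(p, 1.2), "level")
})

test_that("scaling counts tenfold narrows every interval", {
  for (counts in list(c(41, 38, 21), c(2, 5, 3), c(0, 10, 0))) {
    w1 <- credible_interval(posterior_from_counts(counts), 0.95)
    w2 <- credible_interval(posterior_from_counts(counts * 10), 0.95)
    expect_true(all((w2[, "high"] - w2[, "low"]) <
                      (w1[, "high"] - w1[, "low"])))
  }
})

test_that("MCMC sampling agrees with the conjugate closed form", {
  for (counts in list(c(0, 0, 0), c(41, 38, 21), c(3, 90, 7))) {
    m <- mcmc_posterior(counts, seed = 77)
    a <- posterior_from_counts(counts)
    expect_true(all(abs(m$mean - a$mean) < 0.01),
                label = paste("counts", paste(counts, collapse = ",")))
    expect_true(all(abs(rowSums(m$draws) - 1) < 1e-9))  # simplex support
    expect_true(all(m$draws >= 0))
  }
})

test_that("MCMC is deterministic per seed and validates inputs", {
  m1 <- mcmc_posterior(c(5, 2, 9), seed = 3)
  m2 <- mcmc_posterior(c(5, 2, 9), seed = 3)
  expect_identical(m1$draws, m2$draws)
  expect_true(all(m1$diagnostics$rhat < 1.1))
  expect_error(mcmc_posterior(c(1, 1, 1), draws = 10), ">= 1000")
})

test_that("MCMC existence aggregation matches the analytic Beta mean", {
  counts <- c(14, 70, 16)
  m <- mcmc_posterior(counts, seed = 12)
  a <- posterior_from_counts(counts)
  s <- existence_direction(a)
  expect_lt(abs(mean(m$draws[, "left"] + m$draws[, "right"]) - s$exists_mean),
            0.01)
})

test_that("mirror symmetry: swapping pair order swaps left and right", {
  counts <- c(17, 60, 23)
  a <- posterior_from_counts(counts)
  b <- posterior_from_counts(rev(counts))   # canonical order reversed
  expect_equal(a$mean[["left"]], b$mean[["right"]])
  expect_equal(unname(credible_interval(a)["left", ]),
               unname(credible_interval(b)["right", ]))
  sa <- existence_direction(a); sb <- existence_direction(b)
  expect_equal(sa$exists_mean, sb$exists_mean)
  expect_equal(sa$direction_mean, 1 - sb$direction_mean, tolerance = 1e-12)
})
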