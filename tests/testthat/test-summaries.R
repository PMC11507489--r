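test_that("existence and direction Betas follow Dirichlet aggregation", {
  s0 <- existence_direction(posterior_from_counts(c(0, 100, 0)))
  expect_equal(s0$exists_mean, (2 / 3) / 101, tolerance = 1e-12)

  s1 <- existence_direction(posterior_from_counts(c(2, 5, 3)))
  expect_equal(s1$exists_mean, (2 + 3 + 2 / 3) / 11, tolerance = 1e-12)

  s2 <- existence_direction(posterior_from_counts(c(41, 0, 21)))
  expect_equal(s2$direction_mean, (21 + 1 / 3) / (62 + 2 / 3),
               tolerance = 1e-12)
  expect_true(all(c(s1$exists_interval, s1$direction_interval) >= 0))
  expect_lt(s1$exists_interval[1], s1$exists_interval[2])
})

test_that("MAP state is the largest posterior mean, ties to none", {
  p <- posterior_from_counts(c(41, 38, 21))
  expect_equal(map_state(p), "left")
  expect_equal(map_state(posterior_from_counts(c(0, 0, 0))), "none")
  expect_equal(map_state(posterior_from_counts(c(1, 98, 1))), "none")
  expect_equal(map_state(posterior_from_counts(c(30, 0, 30))), "none")
})

test_that("MAP graph thresholds existence and may contain cycles", {
  nodes <- c("A", "B", "C")
  # every graph in the ensemble holds A->B, B->C, C->A is impossible in a
  # DAG ensemble as one graph, but pairs are independent across graphs:
  g1 <- dag(nodes, rbind(c("A", "B"), c("B", "C")))
  g2 <- dag(nodes, rbind(c("C", "A"), c("A", "B")))
  g3 <- dag(nodes, rbind(c("B", "C"), c("C", "A")))
  rep <- report_from_census(count_edge_states(rep(list(g1, g2, g3), 5),
                                              nodes))
  g <- map_graph(rep, threshold = 0.6)
  key <- paste(g$edges[, 1], g$edges[, 2])
  expect_setequal(key, c("A B", "B C", "C A"))   # a directed 3-cycle
  expect_s3_class(g, "digraph")

  expect_equal(nrow(map_graph(rep, threshold = 0.99)$edges), 0L)
  r2 <- report_from_census(count_edge_states(replicate(4, dag(nodes),
                                                       simplify = FALSE)))
  expect_equal(nrow(map_graph(r2, threshold = 0.5)$edges), 0L)
  # threshold 0: every pair whose direction dominates contributes an edge
  expect_equal(nrow(map_graph(rep, threshold = 0)$edges), 3L)
})

test_that("MAP graph orients each pair towards the larger direction mean", {
  nodes <- c("A", "B")
  ens <- c(replicate(9, dag(nodes, rbind(c("A", "B"))), simplify = FALSE),
           replicate(1, dag(nodes, rbind(c("B", "A"))), simplify = FALSE))
  rep <- report_from_census(count_edge_states(ens))
  g <- map_graph(rep, threshold = 0.75)
  expect_identical(unname(g$edges[1, ]), c("A", "B"))
})

test_that("Beta-Binomial baseline: one posterior per ordered pair", {
  nodes <- LETTERS[1:5]
  ens <- replicate(10, dag(nodes, rbind(c("A", "B"))), simplify = FALSE)
  bb <- beta_binomial_posteriors(ens, nodes)
  expect_equal(nrow(bb), 20L)            # n^2 - n ordered pairs
  ab <- bb[bb$from == "A" & bb$to == "B", ]
  ba <- bb[bb$from == "B" & bb$to == "A", ]
  expect_equal(ab$count, 10L)
  expect_equal(ba$count, 0L)             # directions counted independently
  expect_true(ab$selected); expect_false(ba$selected)
  # absent arc, uniform prior: mean 1/(k+2)
  expect_equal(ba$mean, 1 / 12, tolerance = 1e-12)
})

test_that("Beta-Binomial posterior matches frozen Beta(22, 80) quantiles", {
  nodes <- c("A", "B")
  ens <- c(replicate(21, dag(nodes, rbind(c("A", "B"))), simplify = FALSE),
           replicate(79, dag(nodes), simplify = FALSE))
  bb <- beta_binomial_posteriors(ens, nodes)
  ab <- bb[bb$from == "A" & bb$to == "B", ]
  expect_equal(ab$mean, 22 / 102, tolerance = 1e-12)
  expect_equal(ab$low, 0.1418264, tolerance = 1e-5)
  expect_equal(ab$high, 0.3000968, tolerance = 1e-5)
  expect_false(ab$selected)   # most common arc, still below the 50% bar
})
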