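test_that("a single variable yields the empty graph", {
  d <- binary_data(x = c(0, 1, 0, 1))
  g <- hill_climb(d)
  expect_equal(nrow(g$edges), 0L)
})

test_that("independent fair variables stay unconnected (exhaustive check)", {
  set.seed(21)
  d <- binary_data(a = sample(0:1, 1000, TRUE), b = sample(0:1, 1000, TRUE))
  cfg <- score_config("bic")
  g <- hill_climb(d, cfg)
  # oracle: score all three two-node graphs directly
  scores <- vapply(all_dags(c("a", "b")), bic_score, 0, D = d)
  expect_equal(nrow(g$edges), 0L)
  expect_equal(bic_score(g, d), max(scores))
})

test_that("perfectly correlated variables get one edge (exhaustive check)", {
  set.seed(22)
  v <- sample(0:1, 100, TRUE)
  d <- binary_data(a = v, b = v)
  g <- hill_climb(d, score_config("bic"))
  expect_equal(nrow(g$edges), 1L)
  scores <- vapply(all_dags(c("a", "b")), bic_score, 0, D = d)
  expect_equal(bic_score(g, d), max(scores), tolerance = 1e-10)
})

test_that("three-variable search matches brute force or certifies a local optimum", {
  dags3 <- all_dags(c("p", "q", "r"))
  expect_length(dags3, 25L)   # all labelled DAGs on 3 nodes
  set.seed(23)
  for (case in 1:5) {
    p <- sample(0:1, 150, TRUE)
    q <- if (case %% 2) ifelse(stats::runif(150) < 0.85, p, 1 - p)
         else sample(0:1, 150, TRUE)
    r <- ifelse(stats::runif(150) < 0.7, q, sample(0:1, 150, TRUE))
    d <- binary_data(p = p, q = q, r = r)
    for (sc in c("bic", "bdeu")) {
      cfg <- score_config(sc)
      sfun <- if (sc == "bic") function(g) bic_score(g, d)
              else function(g) bdeu_score(g, d, 1)
      g <- hill_climb(d, cfg)
      best <- max(vapply(dags3, sfun, 0))
      hit_best <- isTRUE(all.equal(sfun(g), best, tolerance = 1e-9))
      expect_true(hit_best || is_local_optimum(g, d, sfun),
                  label = sprintf("case %d, %s: global or local optimum", case, sc))
      expect_gte(sfun(g), sfun(dag(d$variables)))  # never worse than empty
    }
  }
})

test_that("search output is acyclic and deterministic", {
  set.seed(24)
  a <- sample(0:1, 200, TRUE)
  b <- ifelse(stats::runif(200) < 0.8, a, 1 - a)
  c_ <- ifelse(stats::runif(200) < 0.8, b, 1 - b)
  d <- binary_data(a = a, b = b, c = c_)
  g1 <- hill_climb(d)
  g2 <- hill_climb(d)
  expect_identical(g1$edges, g2$edges)
  expect_s3_class(g1, "dag")      # dag() construction enforces acyclicity
  g3 <- hill_climb(d, restarts = 3, seed = 99)
  expect_s3_class(g3, "dag")
  expect_gte(bdeu_score(g3, d, 1), bdeu_score(g1, d, 1) - 1e-9)
})

test_that("max_parents caps the in-degree", {
  set.seed(25)
  a <- sample(0:1, 300, TRUE); b <- sample(0:1, 300, TRUE)
  y <- as.integer(xor(a, b))
  d <- binary_data(a = a, b = b, y = y)
  g <- hill_climb(d, score_config("bic", max_parents = 1))
  indeg <- table(factor(g$edges[, 2], levels = d$variables))
  expect_true(all(indeg <= 1))
})

test_that("a pluggable learner feeds the ensemble", {
  d <- binary_data(a = c(0, 1, 0, 1), b = c(0, 1, 1, 0))
  fixed <- function(dd) dag(dd$variables, rbind(c("a", "b")))
  ens <- learn_ensemble(list(d, d, d), learner = fixed)
  expect_length(ens, 3)
  expect_true(all(vapply(ens, function(g) nrow(g$edges) == 1L, NA)))
  expect_error(learn_ensemble(list(d), learner = function(dd) "nope"),
               "must return a dag")
})
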