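test_that("degenerate CPTs force a single configuration", {
  g <- dag(c("A", "B"), rbind(c("A", "B")))
  cpts <- list(
    A = array(c(0, 1), 2, dimnames = list(A = c("0", "1"))),
    B = array(c(1, 0, 0, 1), c(2, 2), dimnames = list(B = c("0", "1"),
                                                      A = c("0", "1"))))
  bn <- discrete_bn(g, cpts)
  D <- forward_sample(bn, 50, seed = 1)
  df <- as.data.frame(D)
  expect_true(all(df$A == "1" & df$B == "1"))
})

test_that("sampling frequencies match the model", {
  bn <- fixture_lucas()
  D <- forward_sample(bn, 10000, seed = 42)
  # isolated fair coin
  f <- mean(as.data.frame(D)$Born_an_Even_Day == "1")
  expect_lt(abs(f - 0.5), 0.02)

  # two-node chain: joint frequencies vs exact product
  g <- dag(c("A", "B"), rbind(c("A", "B")))
  bn2 <- discrete_bn(g, list(
    A = array(c(0.7, 0.3), 2, dimnames = list(A = c("0", "1"))),
    B = array(c(0.9, 0.1, 0.2, 0.8), c(2, 2),
              dimnames = list(B = c("0", "1"), A = c("0", "1")))))
  D2 <- as.data.frame(forward_sample(bn2, 10000, seed = 5))
  joint <- table(D2$A, D2$B) / 10000
  exact <- rbind(c(0.7 * 0.9, 0.7 * 0.1), c(0.3 * 0.2, 0.3 * 0.8))
  expect_true(all(abs(joint - exact) < 0.02))
  # determinism per seed
  expect_identical(forward_sample(bn2, 100, seed = 9)$codes,
                   forward_sample(bn2, 100, seed = 9)$codes)
})

test_that("CPT fitting: closed forms and smoothing", {
  d <- binary_data(x = c(rep(0, 7), rep(1, 3)))
  bn <- fit_cpts(dag("x"), d)
  expect_equal(as.numeric(bn$cpts$x), c(0.7, 0.3))

  # parent config '1' never observed
  d2 <- binary_data(p = rep(0, 10), c = rep(c(0, 1), 5))
  g <- dag(c("p", "c"), rbind(c("p", "c")))
  expect_error(fit_cpts(g, d2, smoothing = 0), "unobserved parent")
  bn2 <- fit_cpts(g, d2, smoothing = 1)
  expect_equal(as.numeric(bn2$cpts$c[, 2]), c(0.5, 0.5))
})

test_that("sample-then-fit recovers the generating CPTs", {
  bn <- fixture_lucas()
  D <- forward_sample(bn, 100000, seed = 13)
  fit <- fit_cpts(bn$graph, D, smoothing = 0.5)
  for (v in bn$graph$nodes) {
    expect_true(all(abs(fit$cpts[[v]] - bn$cpts[[v]]) < 0.02),
                label = paste("CPT recovery for", v))
  }
})

test_that("variable elimination reproduces CPT rows and d-separation", {
  bn <- fixture_five_node()
  expect_equal(unname(infer(bn, "L", c(H = "1"))),
               c(1 - 1 / 400, 1 / 400), tolerance = 1e-12)
  # v-structure A -> C <- B with independent A, B: no evidence on C
  g <- dag(c("A", "B", "C"), rbind(c("A", "C"), c("B", "C")))
  bn2 <- discrete_bn(g, list(
    A = array(c(0.6, 0.4), 2, dimnames = list(A = c("0", "1"))),
    B = array(c(0.2, 0.8), 2, dimnames = list(B = c("0", "1"))),
    C = array(rep(c(0.5, 0.5, 0.9, 0.1), 2), c(2, 2, 2),
              dimnames = list(C = c("0", "1"), A = c("0", "1"),
                              B = c("0", "1")))))
  expect_equal(unname(infer(bn2, "A", c(B = "1"))), c(0.6, 0.4),
               tolerance = 1e-12)
})

test_that("variable elimination equals full-joint enumeration", {
  set.seed(51)
  for (bn in list(fixture_five_node(), fixture_lucas())) {
    vars <- bn$graph$nodes
    for (q in 1:10) {
      target <- sample(vars, 1)
      n_ev <- sample(0:min(3, length(vars) - 1), 1)
      ev_vars <- sample(setdiff(vars, target), n_ev)
      ev <- stats::setNames(
        vapply(ev_vars, function(v) sample(bn$categories[[v]], 1), ""),
        ev_vars)
      got <- infer(bn, target, if (n_ev) ev else NULL)
      want <- enumerate_conditional(bn, target, if (n_ev) ev else NULL)
      expect_equal(unname(got), want, tolerance = 1e-9)
    }
  }
})

test_that("zero-probability evidence is rejected", {
  g <- dag(c("A", "B"), rbind(c("A", "B")))
  bn <- discrete_bn(g, list(
    A = array(c(1, 0), 2, dimnames = list(A = c("0", "1"))),
    B = array(c(1, 0, 0, 1), c(2, 2),
              dimnames = list(B = c("0", "1"), A = c("0", "1")))))
  expect_error(infer(bn, "B", c(A = "1")), "impossible evidence")
  expect_error(infer(bn, "B", c(B = "0")), "target cannot")
})

test_that("confusion counts match a brute-force prediction table", {
  g <- dag(c("A", "B", "C"), rbind(c("A", "C"), c("B", "C")))
  bn <- discrete_bn(g, list(
    A = array(c(0.5, 0.5), 2, dimnames = list(A = c("0", "1"))),
    B = array(c(0.3, 0.7), 2, dimnames = list(B = c("0", "1"))),
    C = array(c(0.9, 0.1, 0.4, 0.6, 0.3, 0.7, 0.05, 0.95), c(2, 2, 2),
              dimnames = list(C = c("0", "1"), A = c("0", "1"),
                              B = c("0", "1")))))
  test <- forward_sample(bn, 100, seed = 8)
  got <- evaluate_inference(bn, test, "C")
  # oracle: enumerate each row's conditional and predict by hand
  df <- as.data.frame(test)
  tp <- tn <- fp <- fn <- 0L
  for (i in 1:100) {
    pr <- enumerate_conditional(bn, "C", c(A = df$A[i], B = df$B[i]))
    pred <- c("0", "1")[which.max(pr)]
    if (df$C[i] == "1") { if (pred == "1") tp <- tp + 1L else fn <- fn + 1L }
    else { if (pred == "1") fp <- fp + 1L else tn <- tn + 1L }
  }
  expect_equal(got$tp, tp); expect_equal(got$tn, tn)
  expect_equal(got$fp, fp); expect_equal(got$fn, fn)
  expect_equal(sum(got$rates), 1, tolerance = 1e-9)

  all_pos <- binary_data(A = rep(1, 5), B = rep(1, 5), C = rep(1, 5))
  det <- evaluate_inference(bn, all_pos, "C")   # model predicts C=1 given A=B=1
  expect_equal(unname(det$rates["tp"]), 1)
})

test_that("required sample size follows the rule of three and the exact bound", {
  expect_identical(required_sample_size(1 / 62500, 0.95, "rule_of_three"),
                   187500L)
  expect_identical(required_sample_size(1, 0.99, "exact"), 1L)
  expect_identical(required_sample_size(0.5, 0.95, "exact"), 5L)
  # monotone: decreasing in p, increasing in confidence
  ps <- c(0.001, 0.01, 0.1, 0.5, 1)
  ns <- vapply(ps, required_sample_size, 0L, confidence = 0.95,
               method = "exact")
  expect_true(all(diff(ns) <= 0))
  cs <- c(0.5, 0.8, 0.95, 0.99)
  ms <- vapply(cs, function(cf) required_sample_size(0.01, cf, "exact"), 0L)
  expect_true(all(diff(ms) >= 0))
  expect_error(required_sample_size(0, 0.95), "p_event")
})

test_that("fixtures satisfy their pinned constraints", {
  bn5 <- fixture_five_node()
  expect_equal(bn5$cpts$L["1", "0"], 1 / 25000)
  expect_equal(bn5$cpts$L["1", "1"], 1 / 400)
  expect_equal(bn5$cpts$B["1", "1"], 1 / 20)
  # rarest printed joint event: (H=0, L=1, C=0) once in 62,500 samples
  p_rare <- enumerate_conditional(bn5, "H")  # just to exercise; use joint:
  joint <- bn5$cpts$H["0"] * bn5$cpts$L["1", "0"] * bn5$cpts$C["0", "1"]
  expect_equal(unname(joint), 1 / 62500, tolerance = 1e-15)

  lucas <- fixture_lucas()
  expect_length(lucas$graph$nodes, 12L)
  expect_equal(nrow(lucas$graph$edges), 12L)
  iso <- "Born_an_Even_Day"
  expect_false(iso %in% c(lucas$graph$edges))
  expect_equal(as.numeric(lucas$cpts[[iso]]), c(0.5, 0.5))
  # every CPT row sums to one (checked for both fixtures by construction)
  for (bn in list(bn5, lucas)) for (v in bn$graph$nodes) {
    cpt <- bn$cpts[[v]]
    sums <- if (length(dim(cpt)) == 1) sum(cpt)
            else apply(cpt, seq_along(dim(cpt))[-1], sum)
    expect_true(all(abs(sums - 1) < 1e-9))
  }
  expect_error(fixture_lucas(cpts = list(
    Anxiety = array(c(0.5, 0.6), 2, dimnames = list(Anxiety = c("0", "1"))))),
    "sum to 1")
  expect_error(fixture_lucas(cpts = list(Nope = 1)), "unknown node")
})

test_that("model serialization round-trips", {
  bn <- fixture_five_node()
  p <- withr::local_tempfile(fileext = ".json")
  write_bn_model(bn, p)
  back <- read_bn_model(p)
  expect_equal(back$graph$edges, bn$graph$edges)
  for (v in bn$graph$nodes) expect_equal(back$cpts[[v]], bn$cpts[[v]])
})
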