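# Single-component PLS: closed-form weights, linear score, Youden
# threshold, strict decision rule.

resp_labels <- function(y01) ifelse(y01 == 1, "responder", "nonresponder")

test_that("fitted weights are unit-norm and point from informative genes", {
  set.seed(41)
  y01 <- rep(c(1, 0), each = 20)
  # gene1 tracks the response exactly, gene2 is noise made exactly
  # orthogonal to the centered response -> W = (1, 0)
  yc <- y01 - mean(y01)
  g2 <- rnorm(40)
  g2 <- g2 - yc * sum(g2 * yc) / sum(yc^2)
  X <- cbind(g1 = y01 + rnorm(40, sd = 1e-6), g2 = g2)
  fw <- fit_weights(X, resp_labels(y01))
  expect_equal(sum(fw$weights^2), 1, tolerance = 1e-9)
  expect_gt(fw$weights["g1"], 0.999)
  expect_lt(abs(fw$weights["g2"]), 1e-3)
  # unit norm across random panels of several sizes
  for (p in 2:5) {
    Xp <- matrix(rnorm(40 * p), 40, p,
                 dimnames = list(NULL, paste0("g", 1:p)))
    fwp <- fit_weights(Xp + y01, resp_labels(y01))
    expect_equal(sum(fwp$weights^2), 1, tolerance = 1e-9)
  }
})

test_that("the sign convention puts responders above nonresponders", {
  set.seed(43)
  y01 <- rep(c(1, 0), each = 25)
  # anti-correlated informative gene: weight must come out negative
  X <- cbind(g1 = -2 * y01 + rnorm(50, sd = 0.3), g2 = rnorm(50))
  fw <- fit_weights(X, resp_labels(y01))
  Xs <- scale(X)
  s <- drop(Xs %*% fw$weights)
  expect_gt(mean(s[y01 == 1]), mean(s[y01 == 0]))
  expect_lt(fw$weights["g1"], 0)
})

test_that("fit_weights matches a grid sweep of the covariance objective", {
  set.seed(47)
  for (i in 1:10) {
    y01 <- sample(rep(c(1, 0), each = 20))
    X <- cbind(g1 = 0.8 * y01 + rnorm(40),
               g2 = -0.5 * y01 + rnorm(40))
    fw <- fit_weights(X, resp_labels(y01))
    wo <- grid_weight_oracle(X, y01)
    ang <- function(w) atan2(w[2], w[1])
    d <- abs(ang(fw$weights) - ang(wo)) %% pi
    expect_lt(min(d, pi - d), 1e-3)
  }
})

test_that("degenerate fits raise informative errors", {
  y <- resp_labels(rep(c(1, 0), each = 5))
  X <- cbind(flat = rep(2, 10), g2 = rnorm(10))
  expect_error(fit_weights(X, y), "flat")
  expect_error(fit_weights(cbind(g1 = rnorm(4), g2 = rnorm(4)),
                           rep("responder", 4)), "single class")
})

test_that("the PLS score is the stated linear combination", {
  model <- structure(list(panel = c("a", "b"),
                          weights = c(a = 1, b = 0),
                          threshold = 0,
                          center = c(a = 0, b = 0),
                          scale = c(a = 1, b = 1),
                          reference_gene = NA, degenerate = FALSE),
                     class = "pls_model")
  X <- matrix(c(2.5, 7), nrow = 1, dimnames = list("s1", c("a", "b")))
  expect_equal(unname(pls_score(model, X)), 2.5)
  expect_equal(unname(pls_score(model, X * 0)), 0)
  # published-style two-gene weights on unit scaled expression
  model$weights <- c(a = -0.8251, b = 0.5650)
  X1 <- matrix(c(1, 1), nrow = 1, dimnames = list("s1", c("a", "b")))
  expect_equal(unname(pls_score(model, X1)), -0.2601)
  expect_error(pls_score(model, X[, 1, drop = FALSE]), "missing panel gene")
})

test_that("select_threshold maximizes Youden's J", {
  y <- resp_labels(c(1, 1, 1, 0, 0))
  expect_equal(as.numeric(select_threshold(c(1, 2, 3, -1, 0), y)), 0.5)
  # all-equal scores: degenerate flag, J = 0
  t0 <- select_threshold(rep(2, 5), y)
  expect_equal(as.numeric(t0), 2)
  expect_true(attr(t0, "degenerate"))
  expect_equal(attr(t0, "youden"), 0)
  # exhaustive oracle on overlapping scores
  set.seed(53)
  for (i in 1:10) {
    s <- round(rnorm(30), 1)
    y01 <- rbinom(30, 1, 0.5)
    if (length(unique(y01)) < 2) next
    got <- select_threshold(s, resp_labels(y01))
    o <- threshold_oracle(s, y01 == 1)
    expect_equal(as.numeric(got), unname(o["t"]))
    expect_equal(attr(got, "youden"), unname(o["j"]), tolerance = 1e-12)
  }
  expect_error(select_threshold(1:4, rep("responder", 4)), "single class")
})

test_that("prediction is strict and translation invariant", {
  set.seed(59)
  y01 <- rep(c(1, 0), each = 10)
  X <- cbind(g1 = 2 * y01 + rnorm(20, sd = 0.2), g2 = rnorm(20))
  model <- pls_fit(X, resp_labels(y01))
  # score exactly at T is a nonresponder call
  s <- pls_score(model, X)
  at_t <- model
  at_t$threshold <- unname(pls_score(model, X[1, , drop = FALSE]))
  expect_equal(unname(predict(at_t, X[1, , drop = FALSE])), "nonresponder")
  # shifting scores and threshold together leaves predictions unchanged
  shifted <- model
  shifted$center <- model$center - 3 * model$scale * model$weights /
    sum(model$weights^2)   # shifts every score by +3
  shifted$threshold <- model$threshold + 3
  expect_equal(predict(shifted, X), predict(model, X))
  # separable training data is perfectly classified
  expect_equal(predict(model, X), resp_labels(y01))
})

test_that("predictions are invariant to affine rescaling of an input gene", {
  set.seed(61)
  y01 <- sample(rep(c(1, 0), each = 15))
  X <- cbind(g1 = y01 + rnorm(30), g2 = -y01 + rnorm(30))
  m1 <- pls_fit(X, resp_labels(y01))
  X2 <- X; X2[, "g1"] <- 100 * X[, "g1"] - 7
  m2 <- pls_fit(X2, resp_labels(y01))
  expect_equal(pls_score(m1, X), pls_score(m2, X2), tolerance = 1e-12)
  expect_equal(predict(m1, X), predict(m2, X2))
})

test_that("recovered weight signs match planted opposite-direction effects", {
  hits <- 0L
  for (i in 1:20) {
    cfg <- sim_config(n_responders = 50, n_nonresponders = 50,
                      effect_size_d = 1.5, within_class_rho = 0,
                      seed = 500 + i)
    ch <- generate_cohort(cfg)
    X <- t(rbind(ch$expr_lnc[ch$truth$signal_lnc_id, , drop = FALSE],
                 ch$expr_mrna[ch$truth$signal_mrna_id, , drop = FALSE]))
    fw <- fit_weights(X, ch$labels$response)
    hits <- hits + (fw$weights[1] > 0 && fw$weights[2] < 0)
  }
  expect_gte(hits, 19L)
})
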