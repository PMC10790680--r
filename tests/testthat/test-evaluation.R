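# ROC/AUC, confusion metrics, cross-validation, DeLong comparison.

test_that("roc_auc matches the all-pairs estimator and the trapezoid", {
  y <- c(rep("responder", 4), rep("nonresponder", 4))
  expect_equal(roc_auc(c(5, 6, 7, 8, 1, 2, 3, 4), y)$auc, 1)
  expect_equal(roc_auc(c(1, 2, 3, 4, 5, 6, 7, 8), y)$auc, 0)
  set.seed(67)
  for (i in 1:10) {
    pos <- rnorm(25, 0.5); neg <- rnorm(15)
    if (i %% 2 == 0) { pos <- round(pos, 1); neg <- round(neg, 1) } # ties
    r <- roc_auc(c(pos, neg), c(rep("responder", 25), rep("nonresponder", 15)))
    expect_equal(r$auc, auc_oracle(pos, neg), tolerance = 1e-12)
    expect_equal(trapezoid_auc(pos, neg), r$auc, tolerance = 1e-12)
    # ROC points are monotone and bracket the unit square
    expect_true(all(diff(r$points$fpr) >= 0))
    expect_true(all(diff(r$points$tpr) >= 0))
    # CI brackets the point estimate
    expect_lte(r$ci[1], r$auc); expect_gte(r$ci[2], r$auc)
    expect_gt(r$se, 0)
  }
  expect_error(roc_auc(1:3, rep("responder", 3)), "both classes")
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(71)
  s <- rnorm(40)
  y <- ifelse(rbinom(40, 1, 0.5) == 1, "responder", "nonresponder")
  a <- roc_auc(s, y)$auc
  expect_equal(roc_auc(exp(s), y)$auc, a, tolerance = 1e-12)
  expect_equal(roc_auc(5 * s - 2, y)$auc, a, tolerance = 1e-12)
})

test_that("the SE and CI reproduce the binormal-free closed forms", {
  # hand-computed Hanley-McNeil SE at auc = 0.8, 10 vs 10
  pos <- c(rep(1, 8), 0, 0); neg <- c(rep(0, 8), 1, 1)
  # build scores with exact auc by construction instead:
  pos <- qnorm(seq(0.05, 0.95, length.out = 10), mean = 1)
  neg <- qnorm(seq(0.05, 0.95, length.out = 10))
  r <- roc_auc(c(pos, neg), c(rep("responder", 10), rep("nonresponder", 10)))
  a <- r$auc
  q1 <- a / (2 - a); q2 <- 2 * a^2 / (1 + a)
  se <- sqrt((a * (1 - a) + 9 * (q1 - a^2) + 9 * (q2 - a^2)) / 100)
  expect_equal(r$se, se, tolerance = 1e-12)
  # perfect separation: zero SE, point CI
  rp <- roc_auc(c(2, 3, 0, 1) + c(10, 10, 0, 0),
                c("responder", "responder", "nonresponder", "nonresponder"))
  expect_equal(rp$se, 0)
  expect_equal(rp$ci, c(1, 1))
})

test_that("confusion_metrics reproduces the printed ratio formulas", {
  expect_equal(unname(confusion_metrics(25, 15, 0, 0)), c(1, 1, 1))
  expect_equal(unname(confusion_metrics(3, 2, 2, 1)), c(0.75, 0.5, 0.625))
  expect_equal(confusion_metrics(6, 4, 2, 2),
               confusion_metrics(18, 12, 6, 6))   # scale invariance
  expect_error(confusion_metrics(0, 5, 1, 0), "sensitivity")
  expect_error(confusion_metrics(5, 0, 0, 1), "specificity")
  expect_error(confusion_metrics(-1, 1, 1, 1), "non-negative")
})

test_that("cross-validation is stratified, exhaustive and seeded", {
  set.seed(73)
  y01 <- rep(c(1, 0), each = 6)
  y <- ifelse(y01 == 1, "responder", "nonresponder")
  X <- cbind(g1 = 3 * y01 + rnorm(12, sd = 0.1),
             g2 = -3 * y01 + rnorm(12, sd = 0.1))
  cv <- cross_validate(X, y, k = 5, seed = 17)
  sizes <- sort(table(cv$fold_assignment), decreasing = TRUE)
  expect_equal(unname(as.integer(sizes)), c(3L, 3L, 2L, 2L, 2L))
  expect_equal(sort(unique(cv$fold_assignment)), 1:5)
  expect_length(cv$fold_assignment, 12L)          # every sample once
  # perfectly separable data: perfect held-out accuracy
  expect_equal(cv$mean_accuracy, 1)
  # same seed, same report; different seed, different folds
  cv2 <- cross_validate(X, y, k = 5, seed = 17)
  expect_identical(cv, cv2)
  cv3 <- cross_validate(X, y, k = 5, seed = 18)
  expect_false(identical(cv$fold_assignment, cv3$fold_assignment))
  expect_error(cross_validate(X, y, k = 1), "at least 2")
})

test_that("folds lacking a class drop undefined metrics with a warning", {
  set.seed(79)
  y01 <- c(rep(1, 3), rep(0, 9))    # 3 responders < k = 5 folds
  y <- ifelse(y01 == 1, "responder", "nonresponder")
  X <- cbind(g1 = 2 * y01 + rnorm(12, sd = 0.3), g2 = rnorm(12))
  expect_warning(cv <- cross_validate(X, y, k = 5, seed = 1),
                 "single class")
  expect_true(anyNA(cv$folds$auc))
  expect_false(is.na(cv$mean_auc))
})

test_that("compare_roc handles identity and rank-identical scores", {
  set.seed(83)
  s <- rnorm(30)
  y <- ifelse(rbinom(30, 1, 0.5) == 1, "responder", "nonresponder")
  same <- compare_roc(s, s, y)
  expect_equal(same$p_value, 1)
  expect_equal(same$auc_a, same$auc_b)
  mono <- compare_roc(s, exp(s) + 5, y)
  expect_equal(mono$auc_a, mono$auc_b)
  expect_equal(mono$p_value, 1)
  expect_error(compare_roc(s, s, rep("responder", 30)), "both classes")
})

test_that("compare_roc agrees with pROC's DeLong implementation", {
  library(pROC)
  set.seed(89)
  for (i in 1:5) {
    y01 <- sample(rep(c(1, 0), each = 20))
    sa <- y01 + rnorm(40)
    sb <- 0.5 * y01 + rnorm(40)
    got <- compare_roc(sa, sb, ifelse(y01 == 1, "responder", "nonresponder"))
    ref <- pROC::roc.test(pROC::roc(y01, sa, quiet = TRUE, direction = "<"),
                          pROC::roc(y01, sb, quiet = TRUE, direction = "<"),
                          method = "delong")
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-9)
    expect_equal(got$auc_a, as.numeric(ref$estimate[1]), tolerance = 1e-12)
  }
})

test_that("compare_roc agrees with a permutation test of the AUC difference", {
  set.seed(97)
  y01 <- sample(rep(c(1, 0), each = 20))
  y <- ifelse(y01 == 1, "responder", "nonresponder")
  sa <- y01 + rnorm(40)
  sb <- 0.3 * y01 + rnorm(40)
  got <- compare_roc(sa, sb, y)
  obs <- abs(got$auc_a - got$auc_b)
  # permutation oracle: swap the two scores within random sample subsets
  B <- 2000
  exceed <- 0L
  for (b in 1:B) {
    swap <- runif(40) < 0.5
    pa <- ifelse(swap, sb, sa); pb <- ifelse(swap, sa, sb)
    da <- auc_oracle(pa[y01 == 1], pa[y01 == 0]) -
      auc_oracle(pb[y01 == 1], pb[y01 == 0])
    exceed <- exceed + (abs(da) >= obs - 1e-12)
  }
  p_perm <- exceed / B
  se <- sqrt(p_perm * (1 - p_perm) / B)
  expect_lt(abs(got$p_value - p_perm), max(4 * se, 0.03))
})

test_that("compare_roc is calibrated under the null", {
  set.seed(103)
  rej <- 0L; B <- 400
  for (b in 1:B) {
    y01 <- sample(rep(c(1, 0), each = 20))
    s <- rnorm(40)
    sa <- s + rnorm(40, sd = 0.8)    # two correlated null scores
    sb <- s + rnorm(40, sd = 0.8)
    p <- compare_roc(sa, sb, ifelse(y01 == 1, "responder",
                                    "nonresponder"))$p_value
    rej <- rej + (p < 0.05)
  }
  # binomial 3-sigma band around 0.05
  expect_lt(abs(rej / B - 0.05), 3 * sqrt(0.05 * 0.95 / B) + 0.01)
})
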