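test_that("response transforms follow the declared link conventions", {
  tb <- data.frame(IST60 = c(10, 20, 30), SOC_moves_4 = c(5, 4, 8),
                   SOC_prob_min = c(8, 5, 11))
  z <- transform_response(tb, "IQ")
  expect_equal(as.numeric(z), c(-1, 0, 1))         # n-1 SD
  expect_equal(mean(z), 0)
  expect_equal(sd(z), 1)
  expect_equal(transform_response(tb, "SOCmove"), c(0.2, 0.25, 0.125))
  # the sample maximum is always attained, so the zero-offset reflection
  # would hit log(0): a half-count offset kicks in with a warning
  expect_warning(y <- transform_response(tb, "SOCprob"), "half-count")
  expect_equal(as.numeric(y)[1], log(11 - 8 + 0.5))
  expect_equal(attr(y, "offset"), 0.5)
  # reflected log of 8 against the instrument maximum of 12: log 4
  tb3 <- data.frame(SOC_prob_min = c(8, 5))
  y3 <- transform_response(tb3, "SOCprob", socprob_max = 12)
  expect_equal(as.numeric(y3)[1], log(4))
})

test_that("back-transforms invert the response transforms exactly", {
  tb <- data.frame(IST60 = c(24.5, 31, 40.2), SOC_moves_4 = c(5.5, 4.1, 7),
                   SOC_prob_min = c(3, 7, 11))
  for (rid in c("IQ", "SOCmove", "SOCprob")) {
    y <- suppressWarnings(transform_response(tb, rid))
    raw <- switch(rid, IQ = tb$IST60, SOCmove = tb$SOC_moves_4,
                  SOCprob = tb$SOC_prob_min)
    expect_equal(back_transform_response(y, rid), raw, tolerance = 1e-12)
  }
})

test_that("the interaction design expands to the declared columns", {
  feats <- simulate_feature_table(4, 4, seed = 1)
  des <- build_design(feats, "IQ")
  # 1 intercept + 4 shared main effects + 2 x (indicator + 7 slopes)
  expect_equal(ncol(des$X), 21)
  expect_true(all(c("(Intercept)", "alpha_am", "alpha_itpc", "sigma_am",
                    "sigma_itpc", "grouphighCog", "grouplowCog",
                    "A_am:highCog", "mu_am:lowCog", "A_am:mu_am:highCog",
                    "A_itpc:mu_itpc:lowCog", "power:lowCog") %in% des$terms))
  # group indicators sum to the intercept column
  expect_equal(des$X[, "grouphighCog"] + des$X[, "grouplowCog"],
               des$X[, "(Intercept)"])
  # interaction columns are literal products
  hi <- feats$group == "highCog"
  expect_equal(des$X[, "A_am:mu_am:highCog"],
               ifelse(hi, feats$A_am * feats$mu_am, 0))
  # permuting rows permutes the design identically
  set.seed(2)
  perm <- sample(nrow(feats))
  expect_equal(build_design(feats[perm, ], "IQ")$X,
               des$X[perm, ], ignore_attr = TRUE)
  # zeroed features leave intercept and indicators only
  f0 <- feats; f0[feature_cols] <- 0
  X0 <- build_design(f0, "IQ")$X
  expect_true(all(X0[, "(Intercept)"] == 1))
  expect_true(all(X0[, setdiff(colnames(X0),
    c("(Intercept)", "grouphighCog", "grouplowCog"))] == 0))
  # single-level group is rejected
  f1 <- feats[feats$group == "highCog", ]
  f1$group <- droplevels(f1$group)
  expect_error(build_design(f1, "IQ"), "two levels")
})

test_that("least-squares fits are exact on noiseless designs", {
  set.seed(61)
  X <- cbind(1, matrix(rnorm(60), 30))
  colnames(X) <- c("(Intercept)", "x1", "x2")
  beta <- c(2, -1, 0.5)
  y <- drop(X %*% beta)
  fit <- fit_glm(X, y)
  expect_equal(fit$terms$estimate, beta, tolerance = 1e-10)
  expect_equal(fit$r2, 1)
  expect_equal(fit$rss, 0, tolerance = 1e-18)
  # orthonormal design: coefficients are X^T y
  Q <- qr.Q(qr(matrix(rnorm(100), 20, 5)))
  colnames(Q) <- paste0("q", 1:5)
  yy <- rnorm(20)
  fq <- fit_glm(Q, yy)
  expect_equal(fq$terms$estimate, unname(drop(crossprod(Q, yy))),
               tolerance = 1e-10)
})

test_that("rank-deficient designs drop named columns and report honestly", {
  set.seed(67)
  X <- cbind(a = rnorm(30), b = rnorm(30))
  X <- cbind(X, dup = X[, "a"])
  y <- rnorm(30)
  expect_warning(fit <- fit_glm(X, y), "dup")
  expect_equal(fit$rank, 2)
  expect_equal(fit$dropped, "dup")
  expect_equal(nrow(fit$terms), 2)
})

test_that("the fitted GLM reproduces coefficients planted through the cognition generator", {
  feats <- simulate_feature_table(83, 95, seed = 12)
  truth <- default_glm_truth()
  cg <- simulate_cognition(truth, feats, noise_sd = 0, seed = 12)
  # SOC mean moves: transform is exactly invertible, so recovery is exact
  y <- as.numeric(transform_response(cg, "SOCmove"))
  suppressWarnings(fit <- fit_glm(build_design(feats, "SOCmove"), y))
  est <- setNames(fit$terms$estimate, fit$terms$term)
  for (nm in names(truth$SOCmove))
    expect_equal(unname(est[nm]), unname(truth$SOCmove[nm]), tolerance = 1e-6)
  other <- setdiff(names(est), names(truth$SOCmove))
  expect_lt(max(abs(est[other])), 1e-6)
})

test_that("coefficient recovery stays unbiased across seeded cohorts", {
  truth <- default_glm_truth()
  ests <- sapply(1:50, function(s) {
    feats <- simulate_feature_table(89, 89, seed = s)
    cg <- simulate_cognition(truth, feats, noise_sd = 0.01, seed = s + 500)
    y <- as.numeric(transform_response(cg, "SOCmove"))
    suppressWarnings(fit <- fit_glm(build_design(feats, "SOCmove"), y))
    setNames(fit$terms$estimate, fit$terms$term)[names(truth$SOCmove)]
  })
  bias <- abs(apply(ests, 1, median) - truth$SOCmove) / abs(truth$SOCmove)
  expect_true(all(bias < 0.05))
})

test_that("model-level statistics agree with the standard linear-model fit", {
  set.seed(71)
  feats <- simulate_feature_table(30, 30, seed = 3)
  X <- build_design(feats, "IQ")$X[, c("(Intercept)", "alpha_am",
                                       "sigma_am", "power:lowCog")]
  y <- rnorm(60)
  fit <- fit_glm(X, y)
  ref <- lm(y ~ X[, -1])
  expect_equal(fit$terms$estimate, unname(coef(ref)), tolerance = 1e-10)
  expect_equal(fit$terms$se, unname(summary(ref)$coefficients[, 2]),
               tolerance = 1e-10)
  expect_equal(fit$r2, summary(ref)$r.squared, tolerance = 1e-10)
  expect_equal(fit$fstat, unname(summary(ref)$fstatistic[1]),
               tolerance = 1e-10)
  expect_equal(fit$loglik, as.numeric(logLik(ref)), tolerance = 1e-10)
})

test_that("two-sample tests match their classical references", {
  x <- c(1.2, 3.1, 2.2, 4.5); y <- c(2.0, 2.9, 5.1)
  tt <- two_sample_tests(x, y, "t")
  ref <- t.test(x, y, var.equal = TRUE)
  expect_equal(tt$statistic, unname(ref$statistic))
  expect_equal(tt$p, ref$p.value)
  # identical samples: t = 0, p = 1
  same <- two_sample_tests(c(1, 2, 3), c(1, 2, 3), "t")
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  # both constant and equal: degenerate flag
  deg <- two_sample_tests(c(2, 2), c(2, 2), "t")
  expect_true(deg$degenerate)
  expect_equal(deg$p, 1)
  # exact rank-sum enumeration: {1,2} vs {3,4} has two-sided p = 1/3
  rs <- two_sample_tests(c(1, 2), c(3, 4), "ranksum")
  expect_equal(rs$p, 1 / 3, tolerance = 1e-12)
  # gross separation is detected
  sep <- two_sample_tests(rnorm(20), rnorm(20) + 50, "t")
  expect_lt(sep$p, 0.001)
})

test_that("Bonferroni thresholds are alpha over m", {
  expect_equal(bonferroni(0.05, 1), 0.05)
  expect_equal(bonferroni(0.05, 16), 0.003125)
  expect_equal(bonferroni(0.05, 5), 0.01)
  expect_error(bonferroni(0.05, 0))
})

test_that("permutation topography p-values are calibrated, saturating and reproducible", {
  set.seed(83)
  A <- matrix(rnorm(10 * 6), 10); B <- matrix(rnorm(12 * 6), 12)
  colnames(A) <- colnames(B) <- paste0("ch", 1:6)
  p1 <- permutation_topography(A, B, n_perm = 400, seed = 5)
  p2 <- permutation_topography(A, B, n_perm = 400, seed = 5)
  expect_identical(p1, p2)
  expect_true(all(p1 > 0 & p1 <= 1))
  # a 10 SD shift on one channel saturates at the add-one floor
  B2 <- B; B2[, 3] <- B2[, 3] + 10
  p3 <- permutation_topography(A, B2, n_perm = 400, seed = 5)
  expect_equal(unname(p3["ch3"]), 1 / 401)
  expect_error(permutation_topography(A[1, , drop = FALSE], B, n_perm = 400))
  expect_error(permutation_topography(A, B, n_perm = 50))
})
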