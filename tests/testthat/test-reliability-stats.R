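test_that("consistency ICC is 1 for identical and offset sessions", {
  m <- cbind(c(1, 3, 5, 7), c(1, 3, 5, 7))
  expect_equal(icc_consistency(m)$icc, 1)
  # fixed between-session offsets are ignored by the consistency form
  m2 <- cbind(c(1, 3, 5, 7), c(1, 3, 5, 7) + 10)
  expect_equal(icc_consistency(m2)$icc, 1)
  expect_error(icc_consistency(matrix(2, 3, 2)), class = "imuagree_degenerate")
  expect_error(icc_consistency(cbind(1:5)), class = "imuagree_precondition")
  expect_error(icc_consistency(cbind(c(1, NA), c(2, 3))),
               class = "imuagree_precondition")
})

test_that("ICC matches an independent two-way ANOVA computation", {
  m <- matrix(c(1, 2, 3, 5, 5, 9, 7, 11, 9, 14), ncol = 2, byrow = TRUE)
  res <- icc_consistency(m)

  # oracle: mean squares from stats::aov on the long layout
  long <- data.frame(y = as.numeric(m),
                     subject = factor(rep(1:5, 2)),
                     session = factor(rep(1:2, each = 5)))
  tab <- summary(stats::aov(y ~ subject + session, data = long))[[1]]
  msr <- tab["subject", "Mean Sq"]; mse <- tab["Residuals", "Mean Sq"]
  k <- 2
  expect_equal(res$icc, (msr - mse) / (msr + (k - 1) * mse), tolerance = 1e-12)
  expect_equal(res$ms_rows, msr, tolerance = 1e-12)
  expect_equal(res$ms_error, mse, tolerance = 1e-12)

  # CI brackets the estimate and respects the F-based endpoints
  expect_lte(res$ci95[1], res$icc)
  expect_gte(res$ci95[2], res$icc)
  f <- msr / mse
  fl <- f / qf(0.975, 4, 4); fu <- f * qf(0.975, 4, 4)
  expect_equal(res$ci95, c((fl - 1) / (fl + 1), (fu - 1) / (fu + 1)),
               tolerance = 1e-12)
})

test_that("average-measures ICC follows the Spearman-Brown relation", {
  set.seed(6)
  m <- matrix(rnorm(60), ncol = 3) + rnorm(20)
  s <- icc_consistency(m, form = "single")$icc
  a <- icc_consistency(m, form = "average")$icc
  expect_equal(a, 3 * s / (1 + 2 * s), tolerance = 1e-12)
})

test_that("SEM formula and classification bands behave at the edges", {
  expect_equal(sem_from_icc(3, 1), 0)
  expect_equal(sem_from_icc(2, 0.75), 1)
  expect_equal(sem_from_icc(0, 0.3), 0)
  expect_error(sem_from_icc(2, 1.1), class = "imuagree_precondition")

  expect_equal(classify_icc(0.75), "excellent")
  expect_equal(classify_icc(0.74), "fair_to_high")
  expect_equal(classify_icc(0.40), "fair_to_high")
  expect_equal(classify_icc(0.39), "poor")
  expect_equal(classify_icc(-0.1), "poor")
  expect_error(classify_icc(1.5), class = "imuagree_precondition")
})

test_that("negative ICC estimates are reported unchanged but classed poor", {
  m <- cbind(c(1, 2, 1.5, 1.8), c(2.1, 1.0, 1.9, 1.2))
  res <- icc_consistency(m)
  expect_lt(res$icc, 0)
  expect_equal(res$class, "poor")
})

test_that("classification proportions use half-up rounding over the case grid", {
  cl45 <- c(rep("excellent", 44), "poor")
  s <- classification_summary(cl45, levels = c("excellent", "fair_to_high", "poor"))
  expect_equal(s$pct[s$class == "poor"], 2.2)

  cl45b <- c(rep("excellent", 38), rep("poor", 7))
  s2 <- classification_summary(cl45b, levels = c("excellent", "fair_to_high", "poor"))
  expect_equal(s2$pct[s2$class == "poor"], 15.6)

  s3 <- classification_summary(rep("excellent", 12),
                               levels = c("excellent", "fair_to_high", "poor"))
  expect_equal(s3$pct, c(100.0, 0.0, 0.0))
  expect_error(classification_summary(character(0)),
               class = "imuagree_precondition")
})

test_that("rounded percentages sum to approximately 100", {
  set.seed(7)
  for (r in 1:20) {
    cl <- sample(c("excellent", "fair_to_high", "poor"), 45, replace = TRUE)
    s <- classification_summary(cl, levels = c("excellent", "fair_to_high", "poor"))
    expect_lte(abs(sum(s$pct) - 100), 0.1 + 1e-9)
  }
})

test_that("sample size shrinks with easier alternatives and more sessions", {
  n_of <- function(rho1, k, method = "exact") {
    reliability_sample_size(0.05, 0.2, k = k, rho0 = 0.4, rho1 = rho1,
                            method = method)
  }
  for (method in c("exact", "approx")) {
    ns <- vapply(c(0.6, 0.7, 0.8, 0.9), n_of, numeric(1), k = 3, method = method)
    expect_true(all(diff(ns) <= 0))
    expect_gte(n_of(0.7, 2, method), n_of(0.7, 3, method))
  }
  expect_error(reliability_sample_size(0.05, 0.2, k = 3, rho0 = 0.7, rho1 = 0.4),
               class = "imuagree_precondition")
})

test_that("exact sample size reaches the target power in simulation", {
  alpha <- 0.05; beta <- 0.2; k <- 3; rho0 <- 0.4; rho1 <- 0.7
  n <- reliability_sample_size(alpha, beta, k, rho0, rho1, method = "exact")
  # Monte-Carlo power of the one-sided F test at the returned n
  set.seed(11)
  crit <- ((1 + (k - 1) * rho0) / (1 - rho0)) * qf(1 - alpha, n - 1, n * (k - 1))
  sb <- sqrt(rho1); sw <- sqrt(1 - rho1)
  rejections <- vapply(1:2000, function(r) {
    y <- rnorm(n, 0, sb) + matrix(rnorm(n * k, 0, sw), n, k)
    msb <- k * var(rowMeans(y))
    msw <- sum((y - rowMeans(y))^2) / (n * (k - 1))
    (msb / msw) > crit
  }, logical(1))
  power <- mean(rejections)
  expect_gte(power, 1 - beta - 0.03)  # MC margin
  # one fewer subject should undershoot the nominal power
  expect_lt(icc_test_power(n - 1, k, rho0, rho1, alpha), 1 - beta)
})
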