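test_that("compute_ci averages classes and applies the overlap rule", {
  expect_equal(compute_ci(c(5, 5, 5, 5))$ci, 5)
  expect_equal(compute_ci(1:5)$ci, 3)
  # heavy overlap with uncountable chromatosomes scores the maximum
  expect_equal(compute_ci(overlap_flag = TRUE)$ci, 5)
  expect_error(compute_ci(), "overlap_flag")
  expect_error(compute_ci(c(2, 6)), "1..5")
})

test_that("predict_pic_from_ci evaluates the log-scale calibration", {
  expect_equal(predict_pic_from_ci(5), exp(-3.362 + 0.659 * 5),
               tolerance = 1e-15)
  expect_equal(predict_pic_from_ci(1), exp(-3.362 + 0.659 * 1),
               tolerance = 1e-15)
  expect_error(predict_pic_from_ci(0), "domain")
  expect_error(predict_pic_from_ci(5.01), "domain")
  # strictly increasing over the valid domain
  grid <- seq(1, 5, by = 0.01)
  expect_true(all(diff(predict_pic_from_ci(grid)) > 0))
  # clamping fires only when the coefficients demand it
  expect_message(p <- predict_pic_from_ci(5, intercept = 0.5),
                 "clamped")
  expect_equal(p, 1)
})

test_that("beta regression reproduces an independent ML fit", {
  # fixed dataset drawn once from the log-link model; reference values
  # computed with an independent maximum-likelihood implementation
  set.seed(2024)
  ci <- rep(seq(1, 5, 0.5), each = 3)
  mu <- exp(-3.362 + 0.659 * ci)
  y <- rbeta(length(ci), mu * 150, (1 - mu) * 150)

  flog <- fit_beta_regression(y, ci, "log")
  expect_equal(unname(flog$coefficients),
               c(-3.27593044, 0.64451555), tolerance = 1e-5)
  expect_equal(flog$phi, 169.86130, tolerance = 1e-4)
  expect_equal(flog$loglik, 58.67281683, tolerance = 1e-6)
  expect_equal(flog$aic, -2 * flog$loglik + 6)

  flogit <- fit_beta_regression(y, ci, "logit")
  expect_equal(unname(flogit$coefficients),
               c(-4.4311407, 1.20793705), tolerance = 1e-5)
  expect_equal(flogit$phi, 29.0677209, tolerance = 1e-4)
  expect_equal(flogit$loglik, 33.82659341, tolerance = 1e-6)
})

test_that("beta regression recovers generating parameters at large n", {
  set.seed(77)
  ci <- sample(seq(1, 5, 0.5), 2000, replace = TRUE)
  mu <- plogis(-1 + 0.5 * ci)
  y <- rbeta(2000, mu * 50, (1 - mu) * 50)
  f <- fit_beta_regression(y, ci, "logit")
  expect_lt(abs(f$coefficients[["intercept"]] - (-1)), 0.05)
  expect_lt(abs(f$coefficients[["slope"]] - 0.5), 0.05)
  expect_gt(f$phi, 40)
  expect_lt(f$phi, 60)

  # loglog link recovery too
  mu2 <- exp(-exp(-(-0.5 + 0.4 * ci)))
  y2 <- rbeta(2000, mu2 * 60, (1 - mu2) * 60)
  f2 <- fit_beta_regression(y2, ci, "loglog")
  expect_lt(abs(f2$coefficients[["slope"]] - 0.4), 0.05)
})

test_that("beta regression is deterministic and guards its contract", {
  set.seed(9)
  ci <- runif(30, 1, 5)
  y <- rbeta(30, 2, 5)
  f1 <- fit_beta_regression(y, ci, "logit")
  f2 <- fit_beta_regression(y, ci, "logit")
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-10)
  expect_identical(f1$coefficients, f2$coefficients)

  expect_error(fit_beta_regression(y, rep(2, 30)), "constant")
  expect_error(fit_beta_regression(y[1:3], ci[1:3]), "4 observations")
  # boundary responses are shrunk, with a message, not an error
  yb <- c(0, y[-1])
  expect_message(fb <- fit_beta_regression(yb, ci, "logit"), "adjusted")
  expect_true(fb$boundary_adjusted)
  expect_true(all(fb$fitted > 0 & fb$fitted < 1))
})

test_that("AIC ranks links and prefers the generating one", {
  set.seed(15)
  ci <- sample(seq(1, 5, 0.5), 200, replace = TRUE)
  mu <- exp(-3.362 + 0.659 * ci)
  y <- rbeta(200, mu * 200, (1 - mu) * 200)
  cmp <- compare_links_aic(y, ci)
  expect_equal(cmp$table$link[1], "log")
  expect_equal(cmp$table$delta_aic[1], 0)
  expect_true(all(diff(cmp$table$aic) >= 0))
  # AIC consistency under refit
  refit <- compare_links_aic(y, ci)
  expect_equal(cmp$table$aic, refit$table$aic, tolerance = 1e-6)
  expect_error(compare_links_aic(y[1:3], ci[1:3]), "4 observations")
})

test_that("Friedman test matches the rank formula and reference oracle", {
  consistent <- matrix(rep(c(10, 20, 30), each = 4), 4)
  f <- friedman_test(consistent)
  expect_equal(f$chi2, 8)
  expect_equal(f$df, 2)

  identical_cols <- matrix(rep(c(3, 1, 4, 1), 3), 4)
  expect_equal(friedman_test(identical_cols)$chi2, 0)

  expect_error(friedman_test(matrix(5, 3, 3)), "tied")

  # tie-free tables also match stats::friedman.test exactly
  set.seed(31)
  for (i in 1:5) {
    m <- matrix(sample(1:100, 18), 6, 3)
    expect_equal(friedman_test(m)$chi2,
                 unname(stats::friedman.test(m)$statistic))
    expect_equal(friedman_test(m)$p,
                 stats::friedman.test(m)$p.value)
  }
  # with ties, match the independent tie-corrected reference
  mt <- matrix(c(1, 1, 2, 3, 2, 2, 1, 3, 3, 3, 2, 1, 2, 2, 1), 5, 3)
  expect_equal(friedman_test(mt)$chi2, friedman_chi2_ref(mt))
})

test_that("Friedman statistic agrees with its reference over permutation orbits", {
  set.seed(41)
  m <- matrix(sample(1:20, 12, TRUE), 4, 3)
  perms <- list(1:3, c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2),
                c(3, 2, 1))
  # every within-block relabelling: implementation equals reference
  for (i in 1:50) {
    pm <- t(vapply(1:4, function(b) m[b, perms[[sample(6, 1)]]],
                   numeric(3)))
    if (length(unique(as.vector(pm))) < 2) next
    expect_equal(friedman_test(pm)$chi2, friedman_chi2_ref(pm))
  }
})

test_that("Wilcoxon signed-rank matches the hand formula and wilcox.test", {
  w <- wilcoxon_signed_rank(c(2, 3, 4, 5, 6), c(1, 1, 1, 1, 1))
  expect_equal(w$W, 15)
  expect_equal(w$Z, (15 - 7.5) / sqrt(13.75), tolerance = 1e-12)

  # antisymmetric differences give Z = 0, p = 1
  a <- c(5, 1, 7, 3)
  b <- c(1, 5, 3, 7)
  wa <- wilcoxon_signed_rank(a, b)
  expect_equal(wa$Z, 0)
  expect_equal(wa$p_two_sided, 1)

  expect_error(wilcoxon_signed_rank(c(1, 2), c(1, 2)), "non-zero")
  expect_error(wilcoxon_signed_rank(1, c(1, 2)), "paired")

  # p-value oracle: stats::wilcox.test normal approximation, no continuity
  set.seed(55)
  for (i in 1:10) {
    x <- round(runif(8, 0, 20))
    y <- round(runif(8, 0, 20))
    if (all(x == y)) next
    mine <- wilcoxon_signed_rank(x, y)
    ref <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE,
                                               exact = FALSE,
                                               correct = FALSE))
    expect_equal(mine$p_two_sided, ref$p.value, tolerance = 1e-10)
    expect_equal(mine$Z, wilcoxon_z_ref(x, y), tolerance = 1e-12)
  }
})

test_that("exact Wilcoxon p equals full sign-flip enumeration", {
  set.seed(66)
  x <- c(3, 9, 2, 7, 8, 1)
  y <- c(1, 4, 4, 2, 2, 5)
  w <- wilcoxon_signed_rank(x, y, exact = TRUE)
  # independent enumeration
  d <- x - y
  r <- rank(abs(d))
  n <- length(d)
  mu <- n * (n + 1) / 4
  Wobs <- sum(r[d > 0])
  cnt <- 0
  for (bits in 0:(2^n - 1)) {
    s <- as.integer(intToBits(bits))[1:n]
    if (abs(sum(r[s == 1]) - mu) >= abs(Wobs - mu) - 1e-12) cnt <- cnt + 1
  }
  expect_equal(w$p_two_sided, cnt / 2^n)
})

test_that("linear concordance recovers exact and noisy linear relations", {
  x <- 1:10
  # lm warns about perfect fits; the values themselves are exact
  exact <- suppressWarnings(linear_concordance(x, x))
  expect_equal(exact$slope, 1)
  expect_equal(exact$r2, 1)

  aff <- suppressWarnings(linear_concordance(x, 2 * x + 1))
  expect_equal(aff$slope, 2)
  expect_equal(aff$intercept, 1)
  expect_equal(aff$r2, 1)

  set.seed(12)
  xs <- runif(50)
  ys <- xs + rnorm(50, 0, 0.01)
  noisy <- linear_concordance(xs, ys)
  expect_lt(abs(noisy$slope - 1), 0.05)
  # closed-form OLS oracle
  slope_ref <- sum((xs - mean(xs)) * (ys - mean(ys))) /
    sum((xs - mean(xs))^2)
  expect_equal(noisy$slope, slope_ref, tolerance = 1e-12)
  expect_error(linear_concordance(rep(1, 5), 1:5), "constant")
})
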