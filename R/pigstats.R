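#' Chromatophore index of a scored region
#'
#' The Hogben-Slome chromatophore index (CI) scores each chromatosome on a
#' 5-class ordinal scale from fully punctate (1) to fully dispersed (5);
#' the region's CI is the arithmetic mean of the per-chromatosome classes.
#' When dispersed chromatosomes overlap so heavily that they cannot be
#' told apart and counted, the CI is recorded as 5, the maximum.
#'
#' @param classifications integer vector of class values in 1..5; may be
#'   empty only when `overlap_flag` is TRUE.
#' @param overlap_flag TRUE when individual chromatosomes could not be
#'   resolved because of overlap.
#' @return an object of class `ci_record` with fields `classifications`,
#'   `overlap_flag`, `ci`.
#' @export
compute_ci <- function(classifications = integer(), overlap_flag = FALSE) {
  if (length(classifications) > 0) {
    if (anyNA(classifications) || !all(classifications %in% 1:5))
      stop("classifications must be integers in 1..5")
  }
  if (overlap_flag && length(classifications) == 0L) {
    ci <- 5
  } else if (length(classifications) == 0L) {
    stop("no classifications given and overlap_flag is FALSE")
  } else {
    ci <- mean(classifications)
  }
  structure(list(classifications = as.integer(classifications),
                 overlap_flag = isTRUE(overlap_flag), ci = ci),
            class = "ci_record")
}

#' Predict pigment cover from a chromatophore index
#'
#' Evaluates the fitted log-link calibration
#' `ln(PiC) = intercept + slope * CI`, i.e.
#' `PiC = exp(intercept + slope * CI)`, clamping to `[0, 1]` (with a
#' message when the clamp fires). The defaults are the published
#' calibration for dark pigment in brown shrimp; the relation is only
#' valid for `1 <= CI <= 5`.
#'
#' @param ci numeric vector of CI values in `[1, 5]`.
#' @param intercept,slope calibration coefficients on the log scale.
#' @return predicted PiC fraction(s) in `[0, 1]`.
#' @export
predict_pic_from_ci <- function(ci, intercept = -3.362, slope = 0.659) {
  if (anyNA(ci) || any(ci < 1 | ci > 5))
    stop("CI outside the calibration's stated domain 1 <= CI <= 5")
  p <- exp(intercept + slope * ci)
  if (any(p > 1) || any(p < 0)) {
    message("predicted PiC clamped to [0, 1]")
    p <- pmin(pmax(p, 0), 1)
  }
  p
}

# link functions for the beta-regression mean; mu_eta is d mu / d eta
.beta_links <- list(
  logit = list(g = stats::qlogis, ginv = stats::plogis,
               mu_eta = function(eta) {
                 mu <- stats::plogis(eta); mu * (1 - mu)
               }),
  log = list(g = log, ginv = exp, mu_eta = exp),
  loglog = list(g = function(mu) -log(-log(mu)),
                ginv = function(eta) exp(-exp(-eta)),
                mu_eta = function(eta) exp(-exp(-eta)) * exp(-eta))
)

#' Beta regression of a proportion on one predictor
#'
#' Maximum-likelihood fit of the beta density parameterized by mean mu and
#' precision phi, `y ~ Beta(mu*phi, (1-mu)*phi)`, with `g(mu) = b0 + b1*x`
#' for `g` one of logit, log, or log-log (`g(mu) = -ln(-ln mu)`). Returns
#' coefficients, phi, the log-likelihood, `AIC = -2 loglik + 2*3`, and a
#' pseudo-R^2 defined as the squared Pearson correlation between the
#' link-transformed (boundary-adjusted) response and the linear predictor.
#'
#' Responses exactly at 0 or 1, where the beta likelihood is undefined, are
#' shrunk with the standard adjustment `y* = (y*(n-1) + 0.5)/n` (a message
#' is emitted). Optimization starts from an OLS fit of the link-transformed
#' response for the coefficients and a method-of-moments value for phi, so
#' refits on the same data are exactly reproducible.
#'
#' @param pic numeric response, fractions in `[0, 1]`; at least 4 values.
#' @param ci numeric predictor (not constant).
#' @param link `"logit"`, `"log"` or `"loglog"`.
#' @return an object of class `betareg_fit`.
#' @export
fit_beta_regression <- function(pic, ci, link = c("logit", "log", "loglog")) {
  link <- match.arg(link)
  if (length(pic) != length(ci)) stop("pic and ci must have equal length")
  if (length(pic) < 4L) stop("need at least 4 observations")
  if (anyNA(pic) || anyNA(ci)) stop("missing values not supported")
  if (any(pic < 0 | pic > 1)) stop("pic values must lie in [0, 1]")
  if (stats::sd(ci) == 0) stop("constant predictor: slope not identifiable")
  n <- length(pic)
  y <- pic
  adjusted <- FALSE
  if (any(y <= 0 | y >= 1)) {
    y <- (y * (n - 1) + 0.5) / n
    adjusted <- TRUE
    message("boundary responses adjusted via y* = (y*(n-1)+0.5)/n")
  }
  L <- .beta_links[[link]]
  gy <- L$g(y)
  start_beta <- stats::coef(stats::lm(gy ~ ci))
  mu0 <- L$ginv(start_beta[1] + start_beta[2] * ci)
  mu0 <- pmin(pmax(mu0, 1e-6), 1 - 1e-6)
  resid_var <- stats::var(y - mu0)
  phi0 <- max(mean(mu0 * (1 - mu0)) / max(resid_var, 1e-10) - 1, 1)

  negll <- function(par) {
    mu <- L$ginv(par[1] + par[2] * ci)
    phi <- exp(par[3])
    if (any(!is.finite(mu)) || any(mu <= 0) || any(mu >= 1) ||
        !is.finite(phi)) return(1e10)
    ll <- sum(stats::dbeta(y, mu * phi, (1 - mu) * phi, log = TRUE))
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  negll_grad <- function(par) {
    eta <- par[1] + par[2] * ci
    mu <- L$ginv(eta)
    phi <- exp(par[3])
    if (any(!is.finite(mu)) || any(mu <= 0) || any(mu >= 1) ||
        !is.finite(phi)) return(rep(0, 3))
    ystar <- log(y) - log1p(-y)
    mustar <- digamma(mu * phi) - digamma((1 - mu) * phi)
    dl_dmu <- phi * (ystar - mustar)
    dmu <- L$mu_eta(eta)
    dl_dphi <- sum(digamma(phi) - mu * digamma(mu * phi) -
                     (1 - mu) * digamma((1 - mu) * phi) +
                     mu * log(y) + (1 - mu) * log1p(-y))
    -c(sum(dl_dmu * dmu), sum(dl_dmu * dmu * ci), dl_dphi * phi)
  }
  start <- c(start_beta[1], start_beta[2], log(phi0))
  # walk the start into the feasible region for links with bounded range
  if (negll(start) >= 1e10) {
    for (shrink in c(0.8, 0.6, 0.4, 0.2, 0.1)) {
      cand <- c(start_beta * shrink + c(L$g(mean(y)) * (1 - shrink), 0),
                log(phi0))
      if (negll(cand) < 1e10) { start <- cand; break }
    }
  }
  if (negll(start) >= 1e10)
    stop("could not find a feasible starting point for link '", link, "'")
  opt <- stats::optim(start, negll, gr = negll_grad, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
  # polish: restart once from the optimum (cheap, and makes refits and
  # near-converged fits land on identical values)
  opt2 <- stats::optim(opt$par, negll, gr = negll_grad, method = "BFGS",
                       control = list(maxit = 500, reltol = 1e-14))
  if (opt2$value <= opt$value) opt <- opt2
  if (opt$convergence != 0) {
    opt3 <- stats::optim(opt$par, negll, method = "Nelder-Mead",
                         control = list(maxit = 2000, reltol = 1e-12))
    if (opt3$value <= opt$value) opt <- opt3
    if (opt$convergence != 0)
      stop("beta-regression optimizer did not converge (code ",
           opt$convergence, ", negloglik ", signif(opt$value, 8), ")")
  }
  beta <- unname(opt$par[1:2])
  phi <- unname(exp(opt$par[3]))
  eta <- beta[1] + beta[2] * ci
  loglik <- -opt$value
  structure(list(
    link = link,
    coefficients = c(intercept = beta[1], slope = beta[2]),
    phi = phi,
    loglik = loglik,
    aic = -2 * loglik + 2 * 3,
    pseudo_r2 = stats::cor(gy, eta)^2,
    fitted = L$ginv(eta),
    n = n,
    boundary_adjusted = adjusted
  ), class = "betareg_fit")
}

#' @export
print.betareg_fit <- function(x, ...) {
  cat(sprintf(
    "Beta regression (%s link, n = %d)\n  g(mu) = %.4f + %.4f * x\n",
    x$link, x$n, x$coefficients[1], x$coefficients[2]))
  cat(sprintf("  phi = %.2f  loglik = %.3f  AIC = %.2f  pseudo-R2 = %.3f\n",
              x$phi, x$loglik, x$aic, x$pseudo_r2))
  invisible(x)
}

#' Compare beta-regression link functions by AIC
#'
#' Fits the logit, log and log-log link models to the same data and ranks
#' them by ascending AIC (lower is better). Exact AIC ties fall back to
#' the fixed link order logit, log, log-log.
#'
#' @inheritParams fit_beta_regression
#' @return an object of class `link_comparison`: `fits` (named list of
#'   [fit_beta_regression] results) and `table` (data.frame with link,
#'   loglik, aic, delta_aic, sorted by AIC).
#' @export
compare_links_aic <- function(pic, ci) {
  links <- c("logit", "log", "loglog")
  fits <- lapply(links, function(l)
    suppressMessages(fit_beta_regression(pic, ci, link = l)))
  names(fits) <- links
  tab <- data.frame(
    link = links,
    loglik = vapply(fits, `[[`, numeric(1), "loglik"),
    aic = vapply(fits, `[[`, numeric(1), "aic"),
    pseudo_r2 = vapply(fits, `[[`, numeric(1), "pseudo_r2")
  )
  tab <- tab[order(tab$aic, match(tab$link, links)), ]
  tab$delta_aic <- tab$aic - tab$aic[1]
  rownames(tab) <- NULL
  structure(list(fits = fits, table = tab), class = "link_comparison")
}

#' @export
print.link_comparison <- function(x, ...) {
  cat("Link comparison (ascending AIC):\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Friedman rank-sum test with tie correction
#'
#' Tests for systematic differences among k related treatments (for
#' example, k observers each scoring the same set of images). Within each
#' block the values are mid-ranked; the chi-square statistic
#' `12/(n k (k+1)) * sum(Rj^2) - 3 n (k+1)` is divided by the tie
#' correction `1 - sum(t^3 - t) / (n k (k^2 - 1))`.
#'
#' @param values numeric matrix, blocks (rows) x treatments (columns);
#'   at least 2 of each.
#' @return list with `chi2`, `df`, `p`.
#' @export
friedman_test <- function(values) {
  values <- as.matrix(values)
  n <- nrow(values); k <- ncol(values)
  if (n < 2 || k < 2) stop("need at least 2 blocks and 2 treatments")
  if (anyNA(values)) stop("missing values not supported")
  if (length(unique(as.vector(values))) < 2)
    stop("all blocks completely tied: statistic undefined")
  r <- t(apply(values, 1, rank))
  Rj <- colSums(r)
  chi <- 12 / (n * k * (k + 1)) * sum(Rj^2) - 3 * n * (k + 1)
  ties <- sum(apply(values, 1, function(row) {
    t <- table(row)
    sum(t^3 - t)
  }))
  C <- 1 - ties / (n * k * (k^2 - 1))
  # every block fully tied: no within-block information, statistic is 0
  chi <- if (C <= 0) 0 else chi / C
  list(chi2 = chi, df = k - 1,
       p = stats::pchisq(chi, k - 1, lower.tail = FALSE))
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Signed mid-ranks of the absolute pairwise differences (zeros dropped),
#' with the normal approximation `Z = (W - mu_W) / sigma_W` using the
#' tie-corrected variance and no continuity correction; `W` is the sum of
#' positive ranks. An exact permutation p-value (all 2^n sign flips) is
#' available for small samples.
#'
#' @param paired_a,paired_b paired numeric vectors.
#' @param exact if TRUE, compute the exact two-sided permutation p-value
#'   instead of the normal approximation (n <= 20).
#' @return list with `n` (non-zero differences), `W`, `Z`, `p_two_sided`.
#' @export
wilcoxon_signed_rank <- function(paired_a, paired_b, exact = FALSE) {
  if (length(paired_a) != length(paired_b)) stop("inputs must be paired")
  d <- paired_a - paired_b
  d <- d[d != 0]
  n <- length(d)
  if (n < 2) stop("need at least 2 non-zero differences")
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  t <- table(r)
  sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(t^3 - t) / 48
  Z <- (W - mu) / sqrt(sig2)
  if (exact) {
    if (n > 20) stop("exact p-value limited to n <= 20")
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    Wall <- as.vector(signs %*% r)
    p <- mean(abs(Wall - mu) >= abs(W - mu) - 1e-12)
  } else {
    p <- min(2 * stats::pnorm(-abs(Z)), 1)
  }
  list(n = n, W = W, Z = Z, p_two_sided = p)
}

#' Linear concordance between two measurement methods
#'
#' Ordinary least squares of `y` on `x`; a slope near 1 with high R^2
#' indicates the two methods agree up to noise (used, for instance, to
#' compare cover measured on raw sRGB images against linearized and
#' contrast-normalized ones).
#'
#' @param x,y paired numeric vectors, at least 3 pairs; `x` not constant.
#' @return list with `slope`, `intercept`, `r2`, `df`, `p`.
#' @export
linear_concordance <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired")
  if (length(x) < 3) stop("need at least 3 pairs")
  if (stats::sd(x) == 0) stop("constant x: slope undefined")
  fit <- stats::lm(y ~ x)
  s <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r2 = s$r.squared,
       df = fit$df.residual,
       p = unname(s$coefficients[2, 4]))
}
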