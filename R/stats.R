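#' Pearson product-moment correlation with sentinel semantics
#'
#' Pairs with missing values are dropped; samples with fewer than 3
#' complete pairs or zero variance return `NA` (the undefined sentinel --
#' never a silent zero).
#'
#' @param x,y numeric vectors of equal length.
#' @return correlation in [-1, 1], or `NA_real_`.
#' @export
pearsonRho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) return(NA_real_)
  if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
  cor(x, y, method = "pearson")
}

#' t-based 95% confidence interval of the mean
#'
#' `mean +/- t(0.975, n-1) * s / sqrt(n)`.
#'
#' @param x numeric sample, `n >= 2`.
#' @return named numeric `c(mean, lo, hi)`.
#' @export
meanCI95 <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 2) stop("meanCI95 requires at least 2 observations")
  m <- mean(x)
  hw <- qt(0.975, n - 1) * sd(x) / sqrt(n)
  c(mean = m, lo = m - hw, hi = m + hw)
}

#' Two-sample tests used in the population comparisons
#'
#' Pooled-variance two-sample t-test, paired t-test, or two-sample
#' Kolmogorov-Smirnov test; all two-tailed, significance threshold 0.05,
#' no multiple-testing correction.
#'
#' @param a,b numeric samples (equal length for `paired_t`).
#' @param kind `"t"`, `"paired_t"` or `"ks"`.
#' @return list with `statistic`, `p.value`, `significant`.
#' @export
twoSampleTests <- function(a, b, kind = c("t", "paired_t", "ks")) {
  kind <- match.arg(kind)
  res <- switch(kind,
    t = {
      if (length(a) < 2 || length(b) < 2) stop("t test requires n >= 2")
      t.test(a, b, var.equal = TRUE)
    },
    paired_t = {
      if (length(a) != length(b)) stop("paired test requires equal lengths")
      if (length(a) < 2) stop("paired t test requires n >= 2")
      if (all(a == b)) list(statistic = c(t = 0), p.value = 1)
      else t.test(a, b, paired = TRUE)
    },
    ks = {
      if (length(a) < 1 || length(b) < 1) stop("ks test requires data")
      suppressWarnings(ks.test(a, b))
    })
  list(statistic = unname(res$statistic), p.value = res$p.value,
       significant = is.finite(res$p.value) && res$p.value < 0.05)
}

#' Maximum-likelihood fit of a gamma or normal family
#'
#' Normal parameters are the closed-form MLE; gamma parameters come from
#' numerical likelihood maximization (`MASS::fitdistr`), reported as shape
#' and scale (matching the Gamma(shape, scale) convention of the
#' initial-condition distributions).
#'
#' @param x numeric sample (`n >= 10`; strictly positive for gamma).
#' @param family `"gamma"` or `"normal"`.
#' @return list of class `FitResult`: `family`, `estimate` (named), and
#'   `loglik`.
#' @export
fitMLE <- function(x, family = c("gamma", "normal")) {
  family <- match.arg(family)
  x <- x[is.finite(x)]
  if (length(x) < 10) stop("fitMLE requires at least 10 observations")
  if (family == "normal") {
    mu <- mean(x)
    sigma <- sqrt(mean((x - mu)^2))   # MLE, not the n-1 estimator
    ll <- sum(stats::dnorm(x, mu, sigma, log = TRUE))
    res <- list(family = "normal", estimate = c(mu = mu, sigma = sigma),
                loglik = ll)
  } else {
    if (any(x <= 0)) stop("gamma fits require strictly positive samples")
    fit <- suppressWarnings(MASS::fitdistr(x, "gamma"))
    shape <- unname(fit$estimate["shape"])
    scale <- 1 / unname(fit$estimate["rate"])
    res <- list(family = "gamma",
                estimate = c(shape = shape, scale = scale),
                loglik = fit$loglik)
  }
  class(res) <- "FitResult"
  res
}

#' @export
print.FitResult <- function(x, ...) {
  cat(sprintf("FitResult (%s): %s, logLik %.2f\n", x$family,
              paste(sprintf("%s=%.4g", names(x$estimate), x$estimate),
                    collapse = ", "), x$loglik))
  invisible(x)
}
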