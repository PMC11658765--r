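# Depth-corrected load phenotypes and their characterisation: population
# differences, Welch two-group contrast, and single-component REML
# SNP-based heritability in the kinship eigenbasis.

#' Depth-corrected residual load phenotype
#'
#' Residuals of the ordinary least squares regression
#' `log(count + 1) ~ log(dedup_total)`, the depth correction applied to raw
#' exogenous read counts before any downstream analysis.
#'
#' @param counts Non-negative integer vector of exogenous read counts.
#' @param dedup_totals Positive vector of deduplicated library sizes, same
#'   length and order as `counts`.
#' @return A `load_phenotype`: data frame with `sample`, `count`,
#'   `dedup_total`, `y` (= log(count+1)), `x` (= log depth), and `residual`.
#' @export
normalize_load <- function(counts, dedup_totals) {
  if (length(counts) != length(dedup_totals)) {
    stop("counts and dedup_totals must have the same length")
  }
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(dedup_totals <= 0)) stop("dedup_totals must be positive")
  x <- log(dedup_totals)
  if (stats::sd(x) == 0) stop("all depths identical: degenerate regression")
  y <- log(counts + 1)
  fit <- stats::lm.fit(cbind(1, x), y)
  ids <- names(counts) %||% as.character(seq_along(counts))
  structure(data.frame(sample = ids, count = as.numeric(counts),
                       dedup_total = as.numeric(dedup_totals),
                       y = y, x = x, residual = unname(fit$residuals),
                       stringsAsFactors = FALSE),
            class = c("load_phenotype", "data.frame"))
}

#' Variance in load explained by population of origin
#'
#' One-way fixed-effects ANOVA of the residual loads on population labels:
#' `R^2 = SS_between / SS_total`, with the F test on (k-1, n-k) degrees of
#' freedom.
#'
#' @param loads Numeric vector of residual loads.
#' @param population_labels Factor or character vector, same length.
#' @return List with `r2`, `F`, `df1`, `df2`, `p`.
#' @export
population_variance <- function(loads, population_labels) {
  f <- factor(population_labels)
  k <- nlevels(f)
  n <- length(loads)
  if (k < 2L) stop("need at least 2 populations")
  if (max(table(f)) < 2L) stop("need at least one population with >= 2 samples")
  grand <- mean(loads)
  means <- tapply(loads, f, mean)
  ssb <- sum(table(f) * (means - grand)^2)
  sst <- sum((loads - grand)^2)
  if (sst == 0) return(list(r2 = 0, F = 0, df1 = k - 1L, df2 = n - k, p = 1))
  r2 <- ssb / sst
  df1 <- k - 1L; df2 <- n - k
  Fst <- (ssb / df1) / ((sst - ssb) / df2)
  p <- stats::pf(Fst, df1, df2, lower.tail = FALSE)
  list(r2 = r2, F = Fst, df1 = df1, df2 = df2, p = p)
}

#' Welch's t-test for unequal variances
#'
#' Direct implementation of the Welch statistic with Satterthwaite degrees
#' of freedom. Degenerate conventions: if both groups have zero variance and
#' equal means, `t = 0, p = 1`; zero variance with different means gives
#' `p = 0`.
#'
#' @param loads Numeric vector.
#' @param binary_group Logical or two-level vector splitting the samples.
#' @return List with `t`, `df`, `p`, `mean_diff` (group1 - group2).
#' @export
welch_test <- function(loads, binary_group) {
  g <- factor(binary_group)
  if (nlevels(g) != 2L) stop("binary_group must have exactly 2 levels")
  x1 <- loads[g == levels(g)[1]]
  x2 <- loads[g == levels(g)[2]]
  if (length(x1) < 2L || length(x2) < 2L) stop("both groups need >= 2 samples")
  v1 <- stats::var(x1) / length(x1)
  v2 <- stats::var(x2) / length(x2)
  md <- mean(x1) - mean(x2)
  if (v1 + v2 == 0) {
    if (md == 0) return(list(t = 0, df = length(loads) - 2L, p = 1,
                             mean_diff = 0))
    return(list(t = sign(md) * Inf, df = length(loads) - 2L, p = 0,
                mean_diff = md))
  }
  tstat <- md / sqrt(v1 + v2)
  df <- (v1 + v2)^2 /
    (v1^2 / (length(x1) - 1L) + v2^2 / (length(x2) - 1L))
  df <- max(df, 1)
  list(t = tstat, df = df,
       p = 2 * stats::pt(-abs(tstat), df), mean_diff = md)
}

# restricted log-likelihood profiled over lambda = sigma_g^2 / sigma_e^2 in
# the kinship eigenbasis (yr, Xr rotated; d eigenvalues). Constant terms in
# lambda are kept so that profile differences are valid chi-square deviates.
reml_loglik <- function(log10_lambda, d, yr, Xr) {
  lambda <- 10^log10_lambda
  w <- 1 / (lambda * d + 1)
  n <- length(yr); p <- ncol(Xr)
  XtWX <- crossprod(Xr, w * Xr)
  XtWy <- crossprod(Xr, w * yr)
  beta <- solve(XtWX, XtWy)
  rss <- sum(w * (yr - Xr %*% beta)^2)
  sigma2e <- rss / (n - p)
  -0.5 * ((n - p) * log(2 * pi * sigma2e) + sum(log(lambda * d + 1)) +
            determinant(XtWX, logarithm = TRUE)$modulus[1] + (n - p))
}

scale_kinship <- function(K, tol = 1e-6) {
  if (!isSymmetric(unname(K), tol = 1e-8)) stop("K must be symmetric")
  K <- (K + t(K)) / 2
  K * (nrow(K) / sum(diag(K)))
}

#' Single-component REML SNP-based heritability
#'
#' Fits `y = mu + g + e` with `g ~ N(0, sigma_g^2 K)` by REML, profiling the
#' restricted likelihood over `log10(lambda)` in [-5, 5] after
#' eigendecomposing the kinship (scaled to mean diagonal 1). The point
#' estimate is `h^2 = lambda / (lambda + 1)`; the 95% confidence interval is
#' obtained by profile-likelihood inversion at the chi-square(1) cutoff,
#' clipped to [0, 1]. Estimates at the lambda grid edge are flagged as
#' boundary cases rather than silently clipped.
#'
#' @param loads Numeric phenotype vector.
#' @param K Kinship matrix (symmetric, positive semi-definite).
#' @param conf Confidence level (default 0.95).
#' @param bounds Search bounds on log10(lambda).
#' @return A `heritability_estimate`: list with `h2`, `lower`, `upper`,
#'   `sigma_g2`, `sigma_e2`, `lambda`, `boundary`, `loglik`.
#' @export
snp_heritability <- function(loads, K, conf = 0.95, bounds = c(-5, 5)) {
  n <- length(loads)
  if (n != nrow(K)) stop("loads and K dimensions differ")
  if (n < 20L) warning("n < 20: heritability estimate will be unstable")
  K <- scale_kinship(K)
  eg <- eigen(K, symmetric = TRUE)
  if (min(eg$values) < -1e-6 * max(abs(eg$values))) {
    stop("K is not positive semi-definite beyond tolerance")
  }
  d <- pmax(eg$values, 0)
  yr <- drop(crossprod(eg$vectors, loads))
  Xr <- crossprod(eg$vectors, matrix(1, n, 1))
  ll <- function(l10) reml_loglik(l10, d, yr, Xr)
  opt <- stats::optimize(ll, interval = bounds, maximum = TRUE, tol = 1e-7)
  l10_hat <- opt$maximum
  ll_max <- opt$objective
  # the optimum can sit at an edge; compare against the edges explicitly,
  # and break a flat (unidentifiable) profile toward lambda = 0: no
  # relatedness signal means no genetic variance component
  for (edge in rev(bounds)) {
    if (ll(edge) >= ll_max - 1e-8) { l10_hat <- edge; ll_max <- ll(edge) }
  }
  lambda <- 10^l10_hat
  h2 <- lambda / (lambda + 1)
  w <- 1 / (lambda * d + 1)
  beta <- sum(w * Xr * yr) / sum(w * Xr^2)
  sigma2e <- sum(w * (yr - Xr * beta)^2) / (n - 1)
  cutoff <- stats::qchisq(conf, 1) / 2
  dev <- function(l10) ll_max - ll(l10) - cutoff
  lower10 <- bounds[1]
  if (l10_hat > bounds[1] + 1e-6 && dev(bounds[1]) > 0) {
    lower10 <- stats::uniroot(dev, c(bounds[1], l10_hat))$root
  }
  upper10 <- bounds[2]
  if (l10_hat < bounds[2] - 1e-6 && dev(bounds[2]) > 0) {
    upper10 <- stats::uniroot(dev, c(l10_hat, bounds[2]))$root
  }
  to_h2 <- function(l10) { l <- 10^l10; l / (l + 1) }
  lower <- if (lower10 == bounds[1]) 0 else to_h2(lower10)
  upper <- if (upper10 == bounds[2]) 1 else to_h2(upper10)
  boundary <- l10_hat <= bounds[1] + 1e-6 || l10_hat >= bounds[2] - 1e-6
  if (boundary && l10_hat <= bounds[1] + 1e-6) h2 <- 0
  if (boundary && l10_hat >= bounds[2] - 1e-6) h2 <- 1
  structure(list(h2 = h2, lower = clip01(lower), upper = clip01(upper),
                 sigma_g2 = lambda * sigma2e, sigma_e2 = sigma2e,
                 lambda = lambda, boundary = boundary, loglik = ll_max),
            class = "heritability_estimate")
}

#' @export
print.heritability_estimate <- function(x, ...) {
  cat(sprintf("h2 = %.3f (%.3f-%.3f)%s\n", x$h2, x$lower, x$upper,
              if (x$boundary) " [boundary]" else ""))
  invisible(x)
}
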