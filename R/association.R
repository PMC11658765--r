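# Linear mixed model association in the kinship eigenbasis. The kinship is
# decomposed once; the variance ratio lambda is estimated by REML under the
# null model and either reused for every predictor (p3d) or re-optimised per
# predictor (exact). The reported test is the Wald test of the predictor
# effect.

#' Fit the null linear mixed model
#'
#' `y = W alpha + g + e`, `g ~ N(0, sigma_g^2 K)`. The kinship (scaled to
#' mean diagonal 1) is eigendecomposed once and lambda = sigma_g^2/sigma_e^2
#' is estimated by 1-D REML optimisation of the rotated profile likelihood.
#'
#' @param y Complete numeric phenotype vector.
#' @param K Kinship matrix.
#' @param covariates Optional numeric matrix of covariates (an intercept is
#'   always added).
#' @param bounds Search bounds on log10(lambda).
#' @return A `null_model`: list with eigenvectors `U`, eigenvalues `d`,
#'   rotated phenotype/design, `lambda0`, `loglik`, and `n`.
#' @export
fit_null_lmm <- function(y, K, covariates = NULL, bounds = c(-5, 5)) {
  n <- length(y)
  if (anyNA(y)) stop("y must be complete (drop missing samples first)")
  if (n != nrow(K)) stop("y and K dimensions differ")
  K <- scale_kinship(K)
  eg <- eigen(K, symmetric = TRUE)
  if (min(eg$values) < -1e-6 * max(abs(eg$values))) {
    stop("K is not positive semi-definite beyond tolerance")
  }
  d <- pmax(eg$values, 0)
  X <- cbind(intercept = rep(1, n), covariates)
  U <- eg$vectors
  yr <- drop(crossprod(U, y))
  Xr <- crossprod(U, X)
  ll <- function(l10) reml_loglik(l10, d, yr, Xr)
  opt <- stats::optimize(ll, interval = bounds, maximum = TRUE, tol = 1e-7)
  l10 <- opt$maximum
  obj <- opt$objective
  # flat/edge profiles resolve toward lambda = 0 (see snp_heritability)
  for (edge in rev(bounds)) if (ll(edge) >= obj - 1e-8) {
    l10 <- edge; obj <- ll(edge)
  }
  if (!is.finite(obj)) {
    stop("non-finite restricted likelihood; lambda bracket [",
         bounds[1], ", ", bounds[2], "]")
  }
  structure(list(U = U, d = d, yr = yr, Xr = Xr, X = X,
                 lambda0 = 10^l10, loglik = obj, n = n, bounds = bounds),
            class = "null_model")
}

wald_one <- function(yr, Xr, xr, d, lambda) {
  w <- 1 / (lambda * d + 1)
  G <- cbind(Xr, xr)
  p <- ncol(G)
  n <- length(yr)
  XtWX <- crossprod(G, w * G)
  XtWy <- crossprod(G, w * yr)
  ch <- tryCatch(chol(XtWX), error = function(e) NULL)
  if (is.null(ch)) return(c(beta = NA_real_, se = NA_real_, p = NA_real_))
  beta <- backsolve(ch, forwardsolve(t(ch), XtWy))
  rss <- sum(w * (yr - G %*% beta)^2)
  df <- n - p
  sigma2 <- rss / df
  inv_last <- 1 / ch[p, p]^2  # [(X'WX)^-1]_pp via the Cholesky factor
  se <- sqrt(sigma2 * inv_last)
  tval <- beta[p] / se
  c(beta = beta[p], se = se, p = 2 * stats::pt(-abs(tval), df))
}

#' Single-predictor mixed model scan (GWA / EWA)
#'
#' Tests each column of `X` as a fixed effect in the rotated mixed model
#' via the Wald test. `mode = "p3d"` reuses the null lambda for every
#' predictor; `mode = "exact"` re-optimises lambda per predictor. For EWA,
#' predictors are methylation fractions used as-is (not genotype-coded).
#' Constant predictors get `p = NA` with a reason code.
#'
#' @param null_model A [fit_null_lmm()] result.
#' @param X Samples x predictors numeric matrix, column-aligned to the
#'   phenotype samples.
#' @param sites Optional data frame with `chrom` and `pos` per predictor
#'   (rows aligned to columns of `X`); results are position-sorted when
#'   given.
#' @param mode `"p3d"` (default) or `"exact"`.
#' @return An `association_result` data frame: `predictor`, `chrom`, `pos`,
#'   `beta`, `se`, `p`, `lambda`, `n`, `reason`.
#' @export
lmm_scan <- function(null_model, X, sites = NULL, mode = c("p3d", "exact")) {
  mode <- match.arg(mode)
  nm <- null_model
  X <- as.matrix(X)
  if (nrow(X) != nm$n) stop("predictors not aligned to samples")
  m <- ncol(X)
  res <- matrix(NA_real_, m, 4,
                dimnames = list(colnames(X), c("beta", "se", "p", "lambda")))
  reason <- rep(NA_character_, m)
  Xr_all <- crossprod(nm$U, X)
  for (j in seq_len(m)) {
    if (stats::sd(X[, j]) == 0) { reason[j] <- "constant_predictor"; next }
    xr <- Xr_all[, j]
    lambda <- nm$lambda0
    if (mode == "exact") {
      G <- cbind(nm$Xr, xr)
      llj <- function(l10) reml_loglik(l10, nm$d, nm$yr, G)
      oj <- stats::optimize(llj, interval = nm$bounds, maximum = TRUE,
                            tol = 1e-6)
      lambda <- 10^oj$maximum
      for (edge in nm$bounds) if (llj(edge) > oj$objective) lambda <- 10^edge
    }
    res[j, ] <- c(wald_one(nm$yr, nm$Xr, xr, nm$d, lambda), lambda)
  }
  out <- data.frame(
    predictor = colnames(X) %||% as.character(seq_len(m)),
    chrom = if (is.null(sites)) NA_character_ else sites$chrom,
    pos = if (is.null(sites)) NA_integer_ else sites$pos,
    beta = res[, "beta"], se = res[, "se"], p = res[, "p"],
    lambda = res[, "lambda"], n = nm$n, reason = reason,
    stringsAsFactors = FALSE)
  if (!is.null(sites)) out <- out[order(out$chrom, out$pos), ]
  rownames(out) <- NULL
  structure(out, class = c("association_result", "data.frame"))
}

#' Genome-wide and suggestive significance thresholds
#'
#' The genome-wide threshold is Bonferroni over the number of unlinked
#' (LD-pruned) variants: `alpha / n_unlinked`. The suggestive threshold is
#' fixed at `-log10(p) = 5`.
#'
#' @param n_unlinked Number of unlinked variants (>= 1).
#' @param alpha Family-wise error rate (default 0.05).
#' @return List with `genomewide_p` and `suggestive_p` (= 1e-5).
#' @export
significance_thresholds <- function(n_unlinked, alpha = 0.05) {
  if (n_unlinked < 1L) stop("n_unlinked must be >= 1")
  list(genomewide_p = alpha / n_unlinked, suggestive_p = 1e-5)
}

#' Write an association result as a tab-separated table
#' @param res An `association_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_association <- function(res, path) {
  utils::write.table(as.data.frame(res), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
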