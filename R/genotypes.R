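# Variant filtering, LD pruning and IBS kinship. Dosages are samples x
# variants; missing calls are mean-imputed per variant only where a complete
# matrix is required (kinship, LD).

variant_maf <- function(dosage) {
  p <- colMeans(dosage, na.rm = TRUE) / 2
  pmin(p, 1 - p)
}

mean_impute <- function(dosage) {
  if (!anyNA(dosage)) return(dosage)
  mu <- colMeans(dosage, na.rm = TRUE)
  idx <- which(is.na(dosage), arr.ind = TRUE)
  dosage[idx] <- mu[idx[, 2]]
  dosage
}

subset_variants <- function(vt, keep) {
  new_variant_table(vt$sites[keep, , drop = FALSE],
                    vt$dosage[, keep, drop = FALSE])
}

#' Filter variants by minor allele frequency
#'
#' MAF is computed on non-missing calls; variants with `MAF < min_maf` are
#' removed (a variant exactly at the threshold is kept).
#'
#' @param variants A `variant_table`.
#' @param min_maf Minimum minor allele frequency.
#' @return Filtered `variant_table`.
#' @export
maf_filter <- function(variants, min_maf = 0.04) {
  maf <- variant_maf(variants$dosage)
  subset_variants(variants, maf >= min_maf)
}

#' Prune variants in linkage disequilibrium
#'
#' Sliding windows of `window` variants, advancing by `step`, within each
#' chromosome. Within a window, while any retained pair has squared Pearson
#' dosage correlation above `r2_max`, the member of the currently worst pair
#' with the lower MAF is removed (tie: the variant at the larger position).
#'
#' @param variants A `variant_table`, position-sorted within chromosomes.
#' @param window Window size in variants (default 50).
#' @param step Window slide in variants (default 5).
#' @param r2_max Maximum tolerated squared correlation (default 0.8).
#' @return Character vector of retained variant ids.
#' @export
ld_prune <- function(variants, window = 50L, step = 5L, r2_max = 0.8) {
  dosage <- mean_impute(variants$dosage)
  maf <- variant_maf(variants$dosage)
  sites <- variants$sites
  retained <- rep(TRUE, nrow(sites))
  for (chr in unique(sites$chrom)) {
    idx <- which(sites$chrom == chr)
    idx <- idx[order(sites$pos[idx])]
    m <- length(idx)
    starts <- if (m <= window) 1L else unique(c(seq(1L, m - window + 1L, by = step),
                                                m - window + 1L))
    for (s in starts) {
      win <- idx[s:min(s + window - 1L, m)]
      repeat {
        live <- win[retained[win]]
        if (length(live) < 2L) break
        cm <- suppressWarnings(stats::cor(dosage[, live, drop = FALSE]))^2
        cm[!is.finite(cm)] <- 0
        diag(cm) <- 0
        worst <- max(cm)
        if (worst <= r2_max) break
        hit <- which(cm == worst, arr.ind = TRUE)[1, ]
        a <- live[hit[1]]; b <- live[hit[2]]
        victim <- if (maf[a] < maf[b]) a
        else if (maf[b] < maf[a]) b
        else if (sites$pos[a] > sites$pos[b]) a else b
        retained[victim] <- FALSE
      }
    }
  }
  sites$id[retained]
}

#' Identity-by-state kinship matrix
#'
#' `K_ij = mean over variants of (2 - |g_i - g_j|) / 2`, computed on
#' per-variant mean-imputed dosages. Identical samples give 1, opposite
#' homozygotes at every variant give 0. `method = "grm"` instead returns the
#' centred/standardised genomic relationship matrix
#' `Z Z' / m` (Z = column-standardised dosages), rescaled to mean diagonal
#' 1; use it when the phenotype model assumes genetic covariance
#' proportional to allelic correlation (e.g. heritability recovery against
#' a causal-variant simulation).
#'
#' @param variants A `variant_table` with at least one variant.
#' @param method `"ibs"` (default) or `"grm"`.
#' @return A `kinship_matrix`: list with `K` (n x n) and `samples`.
#' @export
ibs_kinship <- function(variants, method = c("ibs", "grm")) {
  method <- match.arg(method)
  if (ncol(variants$dosage) == 0L) stop("zero variants: cannot compute kinship")
  if (method == "grm") {
    g <- mean_impute(variants$dosage)
    z <- scale(g)
    z[!is.finite(z)] <- 0  # monomorphic columns
    K <- tcrossprod(z) / ncol(z)
    K <- K * (nrow(K) / sum(diag(K)))
    dimnames(K) <- list(rownames(g), rownames(g))
    return(structure(list(K = K, samples = rownames(g)),
                     class = "kinship_matrix"))
  }
  g <- mean_impute(variants$dosage)
  n <- nrow(g); m <- ncol(g)
  if (all(g %in% c(0, 1, 2))) {
    # integer dosages: sum_v |g_i - g_j| = sum_v (g_i - g_j)^2
    #   - 2 * #(variants with opposite homozygotes), all BLAS-expressible
    q <- rowSums(g^2)
    sq <- outer(q, q, "+") - 2 * tcrossprod(g)
    i0 <- (g == 0) * 1; i2 <- (g == 2) * 1
    opp <- tcrossprod(i0, i2)
    D <- sq - 2 * (opp + t(opp))
    K <- 1 - D / (2 * m)
  } else {
    K <- matrix(0, n, n)
    for (i in seq_len(n)) {
      di <- abs(sweep(g[i:n, , drop = FALSE], 2L, g[i, ]))
      K[i, i:n] <- 1 - rowSums(di) / (2 * m)
      K[i:n, i] <- K[i, i:n]
    }
  }
  dimnames(K) <- list(rownames(g), rownames(g))
  structure(list(K = K, samples = rownames(g)), class = "kinship_matrix")
}

#' @export
print.kinship_matrix <- function(x, ...) {
  cat("kinship_matrix:", nrow(x$K), "samples, mean diagonal",
      sprintf("%.3f", mean(diag(x$K))), "\n")
  invisible(x)
}

#' Write a kinship matrix as a square tab-separated table
#' @param km A `kinship_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_kinship <- function(km, path) {
  utils::write.table(format(km$K, digits = 17), path, sep = "\t",
                     quote = FALSE, col.names = NA)
  invisible(path)
}

#' Read a kinship matrix written by [write_kinship()]
#' @param path Input path.
#' @return A `kinship_matrix`.
#' @export
read_kinship <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                                   row.names = 1, check.names = FALSE))
  structure(list(K = m, samples = rownames(m)), class = "kinship_matrix")
}
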