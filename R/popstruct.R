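# Population structure: VanRaden-style realized relationship, LD regression
# on adjacent markers prior to PCA, and PCA with scaled PC covariates.

#' VanRaden realized relationship (kinship) matrix
#'
#' Genotypes are coded -1/0/1 (hom/het/hom), missing values mean-imputed per
#' locus, columns centered by 2(p - 0.5) with p the frequency of the coded
#' allele, and K = WW' / (2 * sum(p(1-p))). All-missing and monomorphic loci
#' are excluded.
#'
#' @param G genotype matrix (A/B/H/N).
#' @return list with `K` (line x line relatedness) and `p` (allele-frequency
#'   vector used for centering).
#' @export
vanraden_kinship <- function(G) {
  X <- geno_numeric(G, het = "half") * 2 - 1      # -1 / 0 / 1
  p <- colMeans((X + 1) / 2, na.rm = TRUE)
  keep <- !is.na(p) & p > 0 & p < 1
  if (!any(keep)) stop("no polymorphic loci with data")
  X <- X[, keep, drop = FALSE]; p <- p[keep]
  for (j in seq_len(ncol(X))) {
    miss <- is.na(X[, j])
    if (any(miss)) X[miss, j] <- 2 * p[j] - 1
  }
  W <- sweep(X, 2, 2 * (p - 0.5))
  K <- tcrossprod(W) / (2 * sum(p * (1 - p)))
  dimnames(K) <- list(rownames(G), rownames(G))
  list(K = K, p = p)
}

#' LD regression on adjacent markers
#'
#' Replaces each standardized marker by its least-squares residual on up to
#' `k` preceding markers (map order) lying within `ldlimit` Morgans, the
#' pre-PCA correction for marker dependency in LD blocks. `k = 0` returns
#' the input unchanged. Rank-deficient regressions use the minimum-norm
#' least-squares solution.
#'
#' @param X lines x markers numeric matrix, columns in map order.
#' @param k number of preceding markers to regress on.
#' @param ldlimit maximum map interval in Morgans (0.001 M = 0.1 cM).
#' @param positions_cM marker positions in cM (same order as columns).
#' @param linkage_group optional grouping; markers on different groups are
#'   never used as predictors for one another.
#' @return residual matrix, same dimensions as `X`.
#' @export
ld_regress <- function(X, k, ldlimit = 0.001, positions_cM = NULL,
                       linkage_group = NULL) {
  if (k == 0) return(X)
  if (is.null(positions_cM)) positions_cM <- seq_len(ncol(X)) * 0
  if (is.null(linkage_group)) linkage_group <- rep(1L, ncol(X))
  R <- X
  lim_cM <- ldlimit * 100
  for (j in seq_len(ncol(X))) {
    prev <- seq_len(j - 1)
    prev <- prev[linkage_group[prev] == linkage_group[j] &
                   abs(positions_cM[j] - positions_cM[prev]) <= lim_cM]
    prev <- utils::tail(prev, k)
    if (!length(prev)) next
    q <- qr(cbind(1, X[, prev, drop = FALSE]))
    R[, j] <- qr.resid(q, X[, j])
  }
  R
}

#' Principal component analysis of a genotype panel
#'
#' Markers are mean-imputed, centered and (by default) standardized to unit
#' variance, then decomposed by PCA; monomorphic markers are dropped. When a
#' residual matrix from [ld_regress()] is supplied the standardization step
#' has already been applied upstream and can be disabled. Returns
#' eigenvalues, line coordinates, percent variance explained, and the first
#' four PCs scaled per component to [0, 1] for use as structure covariates.
#'
#' @param X genotype matrix (A/B/H/N) or a numeric lines x markers matrix.
#' @param n_pc number of components to report (truncated at the rank).
#' @param standardize divide each marker by its standard deviation.
#' @return list with `eigenvalues`, `coordinates`, `variance_explained`
#'   (percent, all components), and `covariates` (first 4 PCs scaled 0-1).
#' @export
pca_structure <- function(X, n_pc = 10, standardize = TRUE) {
  if (is.character(X)) X <- geno_numeric(X, het = "half")
  if (nrow(X) < 2) stop("need at least 2 lines")
  for (j in seq_len(ncol(X))) {
    miss <- is.na(X[, j])
    if (any(miss)) X[miss, j] <- mean(X[, j], na.rm = TRUE)
  }
  sds <- apply(X, 2, stats::sd)
  X <- X[, sds > 0, drop = FALSE]
  pc <- stats::prcomp(X, center = TRUE, scale. = standardize)
  ev <- pc$sdev^2
  n_pc <- min(n_pc, sum(ev > 1e-12))
  ve <- 100 * ev / sum(ev)
  cov4 <- apply(pc$x[, seq_len(min(4, ncol(pc$x))), drop = FALSE], 2, scale01)
  rownames(cov4) <- rownames(X)
  list(eigenvalues = ev, coordinates = pc$x[, seq_len(n_pc), drop = FALSE],
       variance_explained = ve, covariates = cov4)
}

#' Scale a vector to the unit interval
#'
#' @param x numeric vector.
#' @return `x` rescaled so min(x) = 0 and max(x) = 1.
#' @export
scale01 <- function(x) {
  rng <- range(x)
  if (diff(rng) == 0) return(rep(0, length(x)))
  (x - rng[1]) / diff(rng)
}
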