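# Linkage disequilibrium: plain and structure/kinship-corrected squared
# correlations, map distances averaged over populations, and nonlinear
# decay-model fits (Sved drift-recombination; Hill-Weir drift-mutation with
# sample-size adjustment) giving effective population size and the distance
# at which expected r2 falls to 0.1.

#' Plain squared allele-frequency correlation
#'
#' Squared Pearson correlation of allele dosages over lines complete at both
#' loci. Undefined (NA) when either locus has zero variance or fewer than
#' two complete pairs.
#'
#' @param x,y numeric allele-dosage vectors (0/1, het 0.5) or genotype call
#'   vectors (A/B/H/N).
#' @return r-squared in [0, 1], or NA.
#' @export
r2_plain <- function(x, y) {
  if (is.character(x)) x <- .dosage_vec(x)
  if (is.character(y)) y <- .dosage_vec(y)
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2) return(NA_real_)
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) return(NA_real_)
  stats::cor(x[ok], y[ok])^2
}

.dosage_vec <- function(g) c(A = 0, B = 1, H = 0.5, N = NA_real_)[g]

# Symmetric inverse square root of a kinship matrix; eigenvalues floored,
# with a ridge added first if K is not positive definite.
.k_inv_sqrt <- function(K, floor = 1e-8, ridge = 1e-6) {
  e <- eigen(K, symmetric = TRUE)
  if (min(e$values) < floor) {
    K <- K + diag(ridge, nrow(K))
    e <- eigen(K, symmetric = TRUE)
  }
  v <- pmax(e$values, floor)
  list(ihalf = e$vectors %*% (t(e$vectors) / sqrt(v)),
       inv = e$vectors %*% (t(e$vectors) / v))
}

#' Structure- and/or kinship-corrected r-squared
#'
#' Computes the corrected squared correlation between two loci:
#' with structure covariates `S` only, the squared correlation of ordinary
#' least-squares residuals of each dosage vector on `[1, S]` (r2_s); with a
#' kinship matrix `K` only, the squared correlation of the whitened vectors
#' `K^(-1/2) (x - mu)` with `mu` the generalized-least-squares mean under
#' covariance `K` (r2_v); with both, the whitened GLS residuals on `[1, S]`
#' (r2_sv). With neither, equals [r2_plain()].
#'
#' @param x,y dosage or genotype-call vectors.
#' @param S optional lines x k matrix of scaled PC covariates.
#' @param K optional kinship matrix (made positive definite by a 1e-6 ridge
#'   if needed).
#' @return corrected r-squared, or NA when undefined.
#' @export
r2_corrected <- function(x, y, S = NULL, K = NULL) {
  if (is.character(x)) x <- .dosage_vec(x)
  if (is.character(y)) y <- .dosage_vec(y)
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2) return(NA_real_)
  x <- x[ok]; y <- y[ok]
  S <- if (!is.null(S)) S[ok, , drop = FALSE]
  if (is.null(K)) {
    if (is.null(S)) return(r2_plain(x, y))
    q <- qr(cbind(1, S))
    rx <- qr.resid(q, x); ry <- qr.resid(q, y)
    if (stats::sd(rx) == 0 || stats::sd(ry) == 0) return(NA_real_)
    return(stats::cor(rx, ry)^2)
  }
  K <- K[ok, ok, drop = FALSE]
  kk <- .k_inv_sqrt(K)
  X <- cbind(rep(1, length(x)), S)
  XtKi <- crossprod(X, kk$inv)
  bx <- solve(XtKi %*% X, XtKi %*% x)
  by <- solve(XtKi %*% X, XtKi %*% y)
  zx <- kk$ihalf %*% (x - X %*% bx)
  zy <- kk$ihalf %*% (y - X %*% by)
  if (stats::sd(zx) == 0 || stats::sd(zy) == 0) return(NA_real_)
  stats::cor(zx, zy)[1]^2
}

#' Map distances for a locus pair across population maps
#'
#' Distances are taken within each population map where both loci co-occur
#' on one linkage group; the average and minimum over those populations are
#' returned. A pair never co-mapped is excluded (NAs).
#'
#' @param locusA,locusB locus names.
#' @param maps named list of map data frames.
#' @return list with `avg_distance` and `min_distance` in cM.
#' @export
pair_distances <- function(locusA, locusB, maps) {
  d <- c()
  for (m in maps) {
    ia <- match(locusA, m$locus); ib <- match(locusB, m$locus)
    if (is.na(ia) || is.na(ib)) next
    if (m$linkage_group[ia] != m$linkage_group[ib]) next
    d <- c(d, abs(m$position_cM[ia] - m$position_cM[ib]))
  }
  if (!length(d)) return(list(avg_distance = NA_real_, min_distance = NA_real_))
  list(avg_distance = mean(d), min_distance = min(d))
}

#' Build the LD record table for a mapped panel
#'
#' For every locus pair mapped within `max_cm` (average or minimum distance
#' over the supplied maps), computes the four r-squared estimates: plain,
#' structure-corrected (r2_s), kinship-corrected (r2_v) and both (r2_sv).
#' Missing genotypes are mean-imputed for the corrected estimators, which
#' share one whitening transform across all pairs.
#'
#' @param G genotype matrix for the panel.
#' @param maps named list of map data frames covering the loci of `G`.
#' @param S structure covariates (scaled PCs) or NULL.
#' @param K kinship matrix or NULL.
#' @param max_cm retain pairs with average or minimum distance at or below
#'   this (inclusive).
#' @return data frame (locusA, locusB, avg_distance, min_distance, r2, r2_s,
#'   r2_v, r2_sv).
#' @export
ld_records <- function(G, maps, S = NULL, K = NULL, max_cm = 30) {
  loci <- colnames(G)
  pairs <- list()
  for (i in seq_len(length(loci) - 1)) for (j in (i + 1):length(loci)) {
    d <- pair_distances(loci[i], loci[j], maps)
    if (is.na(d$avg_distance)) next
    if (d$avg_distance > max_cm && d$min_distance > max_cm) next
    pairs[[length(pairs) + 1]] <- data.frame(
      locusA = loci[i], locusB = loci[j],
      avg_distance = d$avg_distance, min_distance = d$min_distance,
      stringsAsFactors = FALSE)
  }
  if (!length(pairs)) stop("no mapped pairs within max_cm")
  tab <- do.call(rbind, pairs)
  X <- geno_numeric(G, het = "half")
  for (jc in seq_len(ncol(X))) {
    miss <- is.na(X[, jc])
    if (any(miss)) X[miss, jc] <- mean(X[, jc], na.rm = TRUE)
  }
  Rs <- Zv <- Zsv <- NULL
  if (!is.null(S)) Rs <- qr.resid(qr(cbind(1, S)), X)
  if (!is.null(K)) {
    kk <- .k_inv_sqrt(K)
    one <- matrix(1, nrow(X), 1)
    Zv <- .gls_whiten(X, one, kk)
    if (!is.null(S)) Zsv <- .gls_whiten(X, cbind(one, S), kk)
  }
  ia <- match(tab$locusA, loci); ib <- match(tab$locusB, loci)
  sq <- function(M) {
    if (is.null(M)) return(NA_real_)
    vapply(seq_len(nrow(tab)), function(k) {
      a <- M[, ia[k]]; b <- M[, ib[k]]
      if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
      stats::cor(a, b)^2
    }, 0)
  }
  tab$r2 <- sq(X)
  tab$r2_s <- sq(Rs)
  tab$r2_v <- sq(Zv)
  tab$r2_sv <- sq(Zsv)
  tab
}

.gls_whiten <- function(X, D, kk) {
  DtKi <- crossprod(D, kk$inv)
  B <- solve(DtKi %*% D, DtKi %*% X)
  kk$ihalf %*% (X - D %*% B)
}

#' Expected r-squared under the LD-decay models
#'
#' `sved_expectation` is the drift-recombination equilibrium curve
#' E = 1/(1 + C); `hillweir_expectation` the drift-mutation curve with
#' sample-size adjustment,
#' E = ((10+C)/((2+C)(11+C))) (1 + ((3+C)(12+12C+C^2))/(n(2+C)(11+C))),
#' where C = 4 Ne c with c the map distance in Morgans and n the number of
#' sampled inbred lines.
#'
#' @param C scaled recombination parameter 4*Ne*c.
#' @param n sample size (lines) for the Hill-Weir adjustment.
#' @export
sved_expectation <- function(C) 1 / (1 + C)

#' @rdname sved_expectation
#' @export
hillweir_expectation <- function(C, n) {
  ((10 + C) / ((2 + C) * (11 + C))) *
    (1 + ((3 + C) * (12 + 12 * C + C^2)) / (n * (2 + C) * (11 + C)))
}

#' Map distance at which expected r-squared reaches a threshold
#'
#' Solves E(C) = `r2` numerically for C and converts to map distance
#' d = 100 * C / (4 * Ne) cM. For the Sved model this agrees with the closed
#' form d = 100 * (1/r2 - 1) / (4 * Ne).
#'
#' @param model `"sved"` or `"hillweir"`.
#' @param Ne effective population size.
#' @param n sample size (required for `"hillweir"`).
#' @param r2 threshold (default 0.1).
#' @return distance in cM.
#' @export
ld_d01 <- function(model = c("sved", "hillweir"), Ne, n = NULL, r2 = 0.1) {
  model <- match.arg(model)
  f <- if (model == "sved") function(C) sved_expectation(C) - r2
  else {
    if (is.null(n)) stop("hillweir requires n")
    function(C) hillweir_expectation(C, n) - r2
  }
  C <- stats::uniroot(f, c(1e-12, 1e9), tol = 1e-12)$root
  100 * C / (4 * Ne)
}

.prep_fit <- function(records, distance_field, r2_field) {
  d <- records[[distance_field]]
  y <- records[[r2_field]]
  ok <- !is.na(d) & !is.na(y) & d <= 30
  if (sum(ok) < 10) stop("need >= 10 records with distance <= 30 cM")
  data.frame(c = d[ok] / 100, r2 = y[ok])
}

#' Fit the Sved drift-recombination LD-decay model
#'
#' Unweighted nonlinear least squares of r2 on E = 1/(1 + 4 Ne c), with c
#' the map distance in Morgans; records beyond 30 cM or with undefined r2
#' are dropped. Returns the effective population size, its standard error,
#' and the distance at which the fitted curve reaches r2 = 0.1.
#'
#' @param records LD record table (see [ld_records()]).
#' @param distance_field `"avg_distance"` or `"min_distance"`.
#' @param r2_field which estimate to fit (r2, r2_s, r2_v, r2_sv).
#' @return object of class `ld_model_fit`: model, Ne, Ne_se, n, d01 (cM).
#' @export
fit_sved <- function(records, distance_field = "avg_distance",
                     r2_field = "r2") {
  dat <- .prep_fit(records, distance_field, r2_field)
  fit <- minpack.lm::nlsLM(r2 ~ 1 / (1 + 4 * Ne * c), data = dat,
                           start = list(Ne = 50),
                           lower = 1e-6, control = list(maxiter = 200))
  co <- summary(fit)$coefficients
  Ne <- co["Ne", "Estimate"]
  structure(list(model = "sved", Ne = Ne, Ne_se = co["Ne", "Std. Error"],
                 n = NA_integer_, d01 = ld_d01("sved", Ne),
                 n_records = nrow(dat)), class = "ld_model_fit")
}

#' Fit the Hill-Weir drift-mutation LD-decay model
#'
#' As [fit_sved()] but with the sample-size-adjusted expectation
#' [hillweir_expectation()]; `n` is the number of inbred lines in the panel.
#'
#' @inheritParams fit_sved
#' @param n sample size used in the adjustment.
#' @return object of class `ld_model_fit`.
#' @export
fit_hillweir <- function(records, n, distance_field = "avg_distance",
                         r2_field = "r2") {
  dat <- .prep_fit(records, distance_field, r2_field)
  fit <- minpack.lm::nlsLM(r2 ~ hillweir_expectation(4 * Ne * c, n),
                           data = dat, start = list(Ne = 50),
                           lower = 1e-6, control = list(maxiter = 200))
  co <- summary(fit)$coefficients
  Ne <- co["Ne", "Estimate"]
  structure(list(model = "hillweir", Ne = Ne,
                 Ne_se = co["Ne", "Std. Error"], n = n,
                 d01 = ld_d01("hillweir", Ne, n), n_records = nrow(dat)),
            class = "ld_model_fit")
}

#' @export
print.ld_model_fit <- function(x, ...) {
  cat(sprintf("%s LD-decay fit: Ne = %.1f (SE %.2f), distance at r2=0.1: %.2f cM (%d pairs)\n",
              x$model, x$Ne, x$Ne_se, x$d01, x$n_records))
  invisible(x)
}
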