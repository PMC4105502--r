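# Independent brute-force oracles used to check the package implementations.

# Genotype matrix from per-line call strings, e.g. geno_from("AABH", "BBHN").
geno_from <- function(..., lines = NULL, loci = NULL) {
  rows <- strsplit(c(...), "", fixed = TRUE)
  G <- do.call(rbind, rows)
  rownames(G) <- lines %||% sprintf("L%02d", seq_len(nrow(G)))
  colnames(G) <- loci %||% sprintf("M%02d", seq_len(ncol(G)))
  G
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Two-sided Fisher exact p by hypergeometric enumeration over all 2x2
# tables with the observed margins. a = both, b = tag1 only, c = tag2 only,
# d = neither.
fisher_enum_p <- function(a, b, c, d) {
  m1 <- a + b; m2 <- a + c; N <- a + b + c + d
  xs <- max(0, m1 + m2 - N):min(m1, m2)
  probs <- dhyper(xs, m2, N - m2, m1)
  p_obs <- dhyper(a, m2, N - m2, m1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# VanRaden kinship by explicit double loop.
vanraden_brute <- function(G) {
  X <- matrix(NA_real_, nrow(G), ncol(G))
  X[G == "A"] <- -1; X[G == "H"] <- 0; X[G == "B"] <- 1
  p <- colMeans((X + 1) / 2, na.rm = TRUE)
  keep <- !is.na(p) & p > 0 & p < 1
  X <- X[, keep, drop = FALSE]; p <- p[keep]
  for (j in seq_len(ncol(X))) X[is.na(X[, j]), j] <- 2 * p[j] - 1
  denom <- 2 * sum(p * (1 - p))
  n <- nrow(G)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    K[i, j] <- sum((X[i, ] - 2 * (p - 0.5)) * (X[j, ] - 2 * (p - 0.5))) / denom
  }
  K
}

# UPGMA by explicit O(n^3) agglomeration; returns the cophenetic matrix of
# merge dissimilarities (ties broken by lexicographic minimum member label).
upgma_brute_cophenetic <- function(D) {
  lab <- rownames(D)
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  d <- D
  coph <- matrix(0, n, n, dimnames = dimnames(D))
  active <- rep(TRUE, n)
  dm <- d
  sizes <- rep(1, n)
  while (sum(active) > 1) {
    best <- NULL; bestv <- Inf; bestlab <- NULL
    ia <- which(active)
    for (i in ia) for (j in ia) {
      if (i >= j) next
      v <- dm[i, j]
      lb <- min(lab[c(clusters[[i]], clusters[[j]])])
      if (v < bestv - 1e-12 ||
          (abs(v - bestv) <= 1e-12 && !is.null(bestlab) && lb < bestlab)) {
        bestv <- v; best <- c(i, j); bestlab <- lb
      }
    }
    i <- best[1]; j <- best[2]
    for (a in clusters[[i]]) for (b in clusters[[j]]) {
      coph[a, b] <- coph[b, a] <- bestv
    }
    for (k in ia) {
      if (k == i || k == j) next
      dm[i, k] <- dm[k, i] <-
        (sizes[i] * dm[i, k] + sizes[j] * dm[j, k]) / (sizes[i] + sizes[j])
    }
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    sizes[i] <- sizes[i] + sizes[j]
    active[j] <- FALSE
  }
  coph
}

# Forward two-locus meiosis oracle, independent of the package simulator:
# haplotypes coded 0..3 (bit 1 = allele at locus 1, bit 2 = locus 2).
ril_two_locus_oracle <- function(r, generation, n_lines) {
  h1 <- rep(0L, n_lines)   # 00
  h2 <- rep(3L, n_lines)   # 11
  gam <- function(a, b) {
    pick1 <- runif(n_lines) < 0.5
    swap <- runif(n_lines) < r
    a1 <- ifelse(pick1, a, b); a2 <- ifelse(xor(pick1, swap), a, b)
    bitwAnd(a1, 1L) + bitwAnd(a2, 2L)
  }
  for (g in seq_len(generation - 1L)) {
    g1 <- gam(h1, h2); g2 <- gam(h1, h2)
    h1 <- g1; h2 <- g2
  }
  l1 <- bitwAnd(h1, 1L) + bitwAnd(h2, 1L)          # 0,1,2 dosage
  l2 <- bitwAnd(bitwShiftR(h1, 1L), 1L) + bitwAnd(bitwShiftR(h2, 1L), 1L)
  hom <- (l1 != 1L) & (l2 != 1L)
  sum((l1[hom] / 2) != (l2[hom] / 2)) / sum(hom)
}

# Corrected r2 by explicit matrix inversion and SVD square root, an
# independent route from the eigen-whitening in the package.
r2_gls_brute <- function(x, y, S = NULL, K) {
  X <- cbind(rep(1, length(x)), S)
  Ki <- solve(K)
  sv <- svd(K)
  Kih <- sv$u %*% diag(1 / sqrt(sv$d), nrow(K)) %*% t(sv$v)
  zx <- Kih %*% (x - X %*% solve(t(X) %*% Ki %*% X) %*% t(X) %*% Ki %*% x)
  zy <- Kih %*% (y - X %*% solve(t(X) %*% Ki %*% X) %*% t(X) %*% Ki %*% y)
  cor(zx, zy)[1]^2
}
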