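# Germplasm-identity diagnostics: allele-matching dissimilarity, UPGMA
# clustering, unknown-sample matching and true-cross verification.

#' Allele-matching dissimilarity
#'
#' For bi-allelic diploid calls, d_ij = 1 - (1/L) * sum_l (m_l / 2), where L
#' is the number of informative loci shared by lines i and j (loci missing
#' in either line are excluded pairwise) and m_l is the number of matching
#' alleles at locus l: 2 for identical calls, 1 for heterozygote vs
#' homozygote, 0 for opposite homozygotes.
#'
#' @param G genotype matrix (A/B/H/N).
#' @return list with `d` (line x line dissimilarity, NA where no shared
#'   informative locus) and `L` (shared-locus counts).
#' @export
allele_match_dissimilarity <- function(G) {
  X <- matrix(NA_real_, nrow(G), ncol(G), dimnames = dimnames(G))
  X[G == "A"] <- 0; X[G == "H"] <- 1; X[G == "B"] <- 2
  n <- nrow(G)
  d <- matrix(NA_real_, n, n, dimnames = list(rownames(G), rownames(G)))
  L <- matrix(0L, n, n, dimnames = list(rownames(G), rownames(G)))
  for (i in seq_len(n)) for (j in i:n) {
    ok <- !is.na(X[i, ]) & !is.na(X[j, ])
    L[i, j] <- L[j, i] <- sum(ok)
    if (any(ok)) {
      m <- 2 - abs(X[i, ok] - X[j, ok])
      d[i, j] <- d[j, i] <- 1 - mean(m / 2)
    }
  }
  diag(d) <- 0
  list(d = d, L = L)
}

#' UPGMA clustering
#'
#' Unweighted pair-group average-linkage clustering of a dissimilarity
#' matrix. Node heights are ultrametric leaf-to-node distances (half the
#' between-cluster dissimilarity at each merge), so two lines at d = 0.2
#' join at height 0.1. Ties are resolved by lexicographic cluster label,
#' making the result deterministic.
#'
#' @param D square dissimilarity matrix (complete, symmetric).
#' @return object of class `gbs_dendrogram`: an `hclust` object (`$hc`) with
#'   half-dissimilarity heights, plus `$labels`.
#' @export
upgma <- function(D) {
  if (any(is.na(D))) stop("dissimilarity matrix has undefined entries")
  lab <- rownames(D)
  ord <- order(lab)
  D <- D[ord, ord]
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  hc$height <- hc$height / 2
  structure(list(hc = hc, labels = hc$labels), class = "gbs_dendrogram")
}

#' @export
print.gbs_dendrogram <- function(x, ...) {
  cat("UPGMA dendrogram with", length(x$labels), "leaves; max height",
      format(max(x$hc$height), digits = 4), "\n")
  invisible(x)
}

#' Export a dendrogram as Newick
#'
#' Branch lengths are height differences between nested nodes, so the tree
#' is ultrametric with leaf depth equal to half the cophenetic
#' dissimilarity.
#'
#' @param dend a [upgma()] result.
#' @param path output file path.
#' @export
dendrogram_newick <- function(dend, path) {
  hc <- dend$hc
  hc$height <- hc$height * 2       # as.phylo halves hclust heights
  phy <- ape::as.phylo(hc)
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Match unknown samples to known lines
#'
#' For each unknown line, reports the known line(s) at dissimilarity at most
#' `max_d`, sorted by d; unknowns with no match are flagged.
#'
#' @param D dissimilarity matrix over all lines.
#' @param known_labels,unknown_labels line names partitioning the rows of
#'   interest.
#' @param max_d match threshold (default 0.05).
#' @return data frame (unknown, known, d, matched).
#' @export
match_unknowns <- function(D, known_labels, unknown_labels, max_d = 0.05) {
  out <- list()
  for (u in unknown_labels) {
    d <- D[u, known_labels]
    hit <- which(!is.na(d) & d <= max_d)
    if (length(hit)) {
      hit <- hit[order(d[hit])]
      out[[length(out) + 1]] <- data.frame(
        unknown = u, known = known_labels[hit], d = unname(d[hit]),
        matched = TRUE, stringsAsFactors = FALSE)
    } else {
      out[[length(out) + 1]] <- data.frame(
        unknown = u, known = NA_character_, d = NA_real_, matched = FALSE,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Verify whether a putative cross is selfed seed of a parent
#'
#' Compares suspected progeny with a parent line: `fraction_variable` is the
#' proportion of loci at which any progeny call differs from the parent's
#' call (missing calls excluded), and the discordance rate is the fraction
#' of individual progeny calls differing from the parent across all
#' progeny-by-locus cells. The verdict is "selfed" when the discordance rate
#' is at or below `error_tolerance` (scoring-error territory) and
#' "segregating" otherwise; a true F2 segregates wherever its parents
#' differed, far above any plausible scoring-error rate. Heterozygote vs
#' homozygote differences count as variable, since F2s are diagnosed chiefly
#' by heterozygosity.
#'
#' @param progeny genotype matrix of suspected progeny (>= 2 lines).
#' @param parent genotype call vector for the parent (same loci).
#' @param error_tolerance scoring-error allowance (default 0.01).
#' @return list with `verdict`, `fraction_variable`, `discordance_rate`,
#'   `n_loci_compared`.
#' @export
verify_cross <- function(progeny, parent, error_tolerance = 0.01) {
  if (nrow(progeny) < 2) stop("need at least 2 progeny")
  loci <- intersect(colnames(progeny), names(parent))
  if (!length(loci)) stop("no shared loci between progeny and parent")
  P <- progeny[, loci, drop = FALSE]
  par <- parent[loci]
  cmp <- P != matrix(par, nrow(P), length(loci), byrow = TRUE)
  cmp[P == "N" | matrix(par == "N", nrow(P), length(loci), byrow = TRUE)] <- NA
  locus_var <- apply(cmp, 2, function(v) any(v, na.rm = TRUE))
  informative <- colSums(!is.na(cmp)) > 0
  fraction_variable <- mean(locus_var[informative])
  discordance <- mean(cmp, na.rm = TRUE)
  verdict <- if (discordance <= error_tolerance) "selfed" else "segregating"
  list(verdict = verdict, fraction_variable = fraction_variable,
       discordance_rate = discordance, n_loci_compared = sum(informative))
}
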