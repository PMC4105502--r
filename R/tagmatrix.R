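# SNP calling from sequence tags: reciprocal tag pairing with a network
# filter, the population-level Fisher exact filter, genotype calling from
# paired tag counts, multi-allelic set detection and catalog merging under a
# stable nomenclature.

#' Tag catalog
#'
#' Container for fixed-length (64 bp) sequence tags, per-line read counts
#' and known/candidate tag pairs.
#'
#' @param tags named character vector of unique, equal-length DNA tags.
#' @param counts line x tag integer matrix of read counts (>= 0), columns
#'   named as in `tags`.
#' @param pairs optional data frame (locus, tag_i, tag_j, snp_offset,
#'   allele_i, allele_j) with 0-based `snp_offset`.
#' @return object of class `tag_catalog`.
#' @export
tag_catalog <- function(tags, counts, pairs = NULL) {
  if (anyDuplicated(tags)) stop("tags must be unique")
  if (length(unique(nchar(tags))) > 1) stop("tags must have equal length")
  if (any(counts < 0)) stop("read counts must be >= 0")
  if (!identical(colnames(counts), names(tags)))
    stop("counts columns must match tag names")
  if (!is.null(pairs)) {
    w <- nchar(tags[1])
    if (any(pairs$snp_offset < 0 | pairs$snp_offset >= w))
      stop("snp_offset out of range")
  }
  structure(list(tags = tags, counts = counts, pairs = pairs),
            class = "tag_catalog")
}

.ham <- function(a, b) sum(a != b)

.tag_char_matrix <- function(tags) {
  do.call(rbind, strsplit(unname(tags), "", fixed = TRUE))
}

#' Pair tags into candidate SNPs
#'
#' Tags supported by at least `min_tag_count` reads in total are compared
#' all-against-all; pairs differing at no more than `max_mismatch` bases are
#' linked. Tags falling in mismatch networks of more than two members
#' (complex multi-locus families) are discarded; the surviving reciprocal
#' pairs become candidate SNP calls.
#'
#' @param catalog a [tag_catalog()].
#' @param max_mismatch maximum differing bases within a pair.
#' @param min_tag_count minimum total reads supporting a tag.
#' @return data frame of candidate SNP calls (name, context, alleles,
#'   snp_offset, tag_i, tag_j, p_value, source); names are assigned later by
#'   [assign_snp_names()].
#' @export
pair_tags <- function(catalog, max_mismatch = 1, min_tag_count = 10) {
  stopifnot(inherits(catalog, "tag_catalog"))
  keep <- colSums(catalog$counts) >= min_tag_count
  tags <- catalog$tags[keep]
  if (length(tags) < 2) return(.empty_snp_calls())
  M <- .tag_char_matrix(tags)
  nt <- length(tags)
  edges <- NULL
  for (i in seq_len(nt - 1)) {
    d <- rowSums(M[(i + 1):nt, , drop = FALSE] !=
                   matrix(M[i, ], nt - i, ncol(M), byrow = TRUE))
    hit <- which(d <= max_mismatch & d > 0)
    if (length(hit)) edges <- rbind(edges, cbind(i, i + hit))
  }
  if (is.null(edges)) return(.empty_snp_calls())
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, nt - igraph::vcount(g)))
  comp <- igraph::components(g)
  out <- list()
  for (k in which(comp$csize == 2)) {
    pr <- sort(which(comp$membership == k))
    diffs <- which(M[pr[1], ] != M[pr[2], ])
    out[[length(out) + 1]] <- data.frame(
      name = NA_character_,
      context = .bracket_context(M[pr[1], ], M[pr[2], ], diffs[1]),
      alleles = paste(sort(c(M[pr[1], diffs[1]], M[pr[2], diffs[1]])),
                      collapse = "/"),
      snp_offset = diffs[1] - 1L,
      tag_i = names(tags)[pr[1]], tag_j = names(tags)[pr[2]],
      p_value = NA_real_, source = "pairwise", stringsAsFactors = FALSE)
  }
  if (!length(out)) return(.empty_snp_calls())
  do.call(rbind, out)
}

.empty_snp_calls <- function() {
  data.frame(name = character(), context = character(), alleles = character(),
             snp_offset = integer(), tag_i = character(), tag_j = character(),
             p_value = numeric(), source = character(),
             stringsAsFactors = FALSE)
}

# "ACGT[A/C]GTCA..." notation; pos is 1-based within the split sequence.
.bracket_context <- function(s1, s2, pos) {
  a <- sort(c(s1[pos], s2[pos]))
  paste0(paste(s1[seq_len(pos - 1)], collapse = ""),
         "[", a[1], "/", a[2], "]",
         paste(s1[seq_len(length(s1) - pos) + pos], collapse = ""))
}

#' Population-level Fisher exact filter for a candidate SNP
#'
#' For a putative allelic tag pair, lines are tallied in a 2x2 table
#' (tag 1 only, tag 2 only, both, neither) and the two-sided Fisher exact
#' test of independence applied. In a population of inbred lines, truly
#' allelic tags are strongly negatively associated, so the null of
#' independence is rejected; the SNP is accepted iff p < `alpha`.
#'
#' @param presence lines x 2 logical (or 0/1) matrix of tag presence.
#' @param alpha significance threshold (default 0.001).
#' @param count_empty_as_neither whether lines lacking both tags enter the
#'   "neither" cell (default) or are excluded.
#' @return list with `accepted`, `p_value` and the 2x2 `table`.
#' @export
fisher_population_filter <- function(presence, alpha = 0.001,
                                     count_empty_as_neither = TRUE) {
  presence <- matrix(as.logical(presence), ncol = 2)
  if (nrow(presence) == 0) stop("empty presence table")
  if (sum(rowSums(presence) > 0) < 2)
    stop("need at least 2 lines with an observed tag")
  if (!count_empty_as_neither)
    presence <- presence[rowSums(presence) > 0, , drop = FALSE]
  tab <- table(factor(presence[, 1], levels = c(TRUE, FALSE)),
               factor(presence[, 2], levels = c(TRUE, FALSE)))
  p <- stats::fisher.test(tab, alternative = "two.sided")$p.value
  list(accepted = p < alpha, p_value = p, table = tab)
}

#' Call genotypes from paired tag counts
#'
#' Per line and tag pair with counts (c1, c2): missing if c1 + c2 = 0;
#' heterozygous if both tags are seen and min(c1, c2)/(c1 + c2) exceeds
#' `error_tolerance` (a minor-tag fraction at or below the tolerance is
#' attributed to sequencing error); otherwise homozygous for the majority
#' tag.
#'
#' @param catalog a [tag_catalog()] with `pairs`.
#' @param error_tolerance minor-read fraction attributed to error.
#' @return genotype matrix (A/B/H/N), loci named by `pairs$locus`.
#' @export
call_genotypes <- function(catalog, error_tolerance = 0.02) {
  stopifnot(inherits(catalog, "tag_catalog"))
  if (is.null(catalog$pairs)) stop("catalog has no tag pairs")
  pr <- catalog$pairs
  c1 <- catalog$counts[, pr$tag_i, drop = FALSE]
  c2 <- catalog$counts[, pr$tag_j, drop = FALSE]
  tot <- c1 + c2
  minor <- pmin(c1, c2)
  G <- matrix("N", nrow(c1), nrow(pr),
              dimnames = list(rownames(catalog$counts), pr$locus))
  het <- tot > 0 & c1 > 0 & c2 > 0 & minor / tot > error_tolerance
  homA <- tot > 0 & !het & c1 >= c2
  homB <- tot > 0 & !het & c2 > c1
  G[het] <- "H"; G[homA] <- "A"; G[homB] <- "B"
  G
}

.mask_context <- function(context) {
  sub("\\[[ACGT]/[ACGT]\\]", "[*]", context)
}

.context_alleles <- function(context) {
  m <- regmatches(context, regexpr("\\[[ACGT]/[ACGT]\\]", context))
  strsplit(gsub("[][]", "", m), "/", fixed = TRUE)[[1]]
}

#' Detect tri- and tetra-allelic SNP sets
#'
#' Groups bi-allelic SNP calls whose context sequences are identical except
#' at the SNP position. A group whose union of alleles has exactly three
#' distinct bases is a tri-allelic set; four, a tetra-allelic set. Groups
#' with identical allele pairs are duplicates, not multi-allelic sets.
#'
#' @param snps SNP-call data frame (needs `context`, `alleles`, `name`).
#' @return list with `tri_sets` and `tetra_sets`, each a list of data frames
#'   (the member SNP calls).
#' @export
detect_multiallelic <- function(snps) {
  if (!nrow(snps)) return(list(tri_sets = list(), tetra_sets = list()))
  key <- .mask_context(snps$context)
  tri <- list(); tetra <- list()
  for (grp in split(seq_len(nrow(snps)), key)) {
    if (length(grp) < 2) next
    alleles <- unique(unlist(strsplit(snps$alleles[grp], "/", fixed = TRUE)))
    if (length(alleles) == 3) tri[[length(tri) + 1]] <- snps[grp, ]
    if (length(alleles) == 4) tetra[[length(tetra) + 1]] <- snps[grp, ]
  }
  list(tri_sets = tri, tetra_sets = tetra)
}

.revcomp <- function(s) {
  chartr("ACGT", "TGCA",
         vapply(lapply(strsplit(s, "", fixed = TRUE), rev), paste,
                "", collapse = ""))
}

# Strand-canonical key: lexicographic minimum of the bracket context and its
# reverse complement (alleles sorted on each strand).
.canonical_key <- function(context) {
  fwd <- vapply(context, function(ctx) {
    a <- sort(.context_alleles(ctx))
    sub("\\[[ACGT]/[ACGT]\\]", paste0("[", a[1], "/", a[2], "]"), ctx)
  }, "", USE.NAMES = FALSE)
  rev <- vapply(fwd, function(ctx) {
    parts <- strsplit(ctx, "[][]")[[1]]   # left, "X/Y", right
    a <- sort(chartr("ACGT", "TGCA", strsplit(parts[2], "/")[[1]]))
    paste0(.revcomp(parts[3]), "[", a[1], "/", a[2], "]", .revcomp(parts[1]))
  }, "", USE.NAMES = FALSE)
  pmin(fwd, rev)
}

#' Assign stable SNP names
#'
#' Names are a fixed prefix plus a zero-padded sequential index in catalog
#' insertion order; once assigned, a name is preserved across merges.
#'
#' @param snps SNP-call data frame.
#' @param prefix name prefix.
#' @param start first index to assign.
#' @return `snps` with `name` filled for previously unnamed records.
#' @export
assign_snp_names <- function(snps, prefix = "GBS", start = 1L) {
  need <- is.na(snps$name)
  snps$name[need] <- sprintf("%s%06d", prefix, seq_len(sum(need)) + start - 1L)
  if (anyDuplicated(snps$name)) stop("duplicate SNP names after assignment")
  snps
}

#' Merge SNP catalogs under a cumulative nomenclature
#'
#' SNPs with identical strand-canonical context (lexicographic minimum of
#' the context and its reverse complement) and alleles are unified under the
#' earlier-assigned name, with `source` set to "both" when the record came
#' from different pipelines; records new to `b` receive the next sequential
#' names. Merging is idempotent: `merge_catalogs(merge_catalogs(a, b), b)`
#' equals `merge_catalogs(a, b)`.
#'
#' @param a,b SNP-call data frames with unique names within each input.
#' @param prefix name prefix for newly assigned names.
#' @return merged SNP-call data frame.
#' @export
merge_catalogs <- function(a, b, prefix = "GBS") {
  for (x in list(a, b)) if (anyDuplicated(stats::na.omit(x$name)))
    stop("names must be unique within each input catalog")
  a$.key <- .canonical_key(a$context)
  b$.key <- .canonical_key(b$context)
  if (anyDuplicated(a$.key))
    a <- a[!duplicated(a$.key), ]
  clash <- intersect(stats::na.omit(a$name), stats::na.omit(b$name))
  for (nm in clash) {
    if (a$.key[match(nm, a$name)] != b$.key[match(nm, b$name)])
      stop("name collision with differing context: ", nm,
           " (catalog corruption)")
  }
  hit <- match(b$.key, a$.key)
  both <- !is.na(hit)
  if (any(both)) {
    differs <- a$source[hit[both]] != b$source[both]
    a$source[hit[both]][differs] <- "both"
  }
  new <- b[which(!both)[!duplicated(b$.key[!both])], , drop = FALSE]
  new$name <- rep(NA_character_, nrow(new))
  idx <- suppressWarnings(
    max(c(0L, as.integer(sub(paste0("^", prefix), "",
                             stats::na.omit(a$name)))), na.rm = TRUE))
  out <- rbind(a, new)
  out <- assign_snp_names(out, prefix = prefix, start = idx + 1L)
  out$.key <- NULL
  rownames(out) <- NULL
  out
}
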