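# Per-locus statistics, population-specific filtering, the depth-index
# convention, and the depth / sample-size experiments.

#' Per-locus completeness, minor allele frequency and heterozygosity
#'
#' Completeness is the fraction of lines with a call (100% minus % missing).
#' MAF counts a heterozygote as one copy of each allele, missing calls
#' excluded. Heterozygosity is the fraction of called lines that are
#' heterozygous. A locus with zero calls gets completeness 0 and NA for maf
#' and het.
#'
#' @param G genotype matrix (A/B/H/N).
#' @return data frame (rownames = loci) with completeness, maf, het, n_called.
#' @export
locus_stats <- function(G) {
  validate_genotype_matrix(G)
  nA <- colSums(G == "A"); nB <- colSums(G == "B"); nH <- colSums(G == "H")
  called <- nA + nB + nH
  a1 <- 2 * nA + nH; a2 <- 2 * nB + nH
  maf <- ifelse(called > 0, pmin(a1, a2) / (a1 + a2), NA_real_)
  het <- ifelse(called > 0, nH / called, NA_real_)
  data.frame(completeness = called / nrow(G), maf = maf, het = het,
             n_called = called, row.names = colnames(G))
}

#' Filter loci on completeness, MAF and heterozygosity
#'
#' Keeps loci with completeness >= `min_completeness`, MAF >= `min_maf` and
#' heterozygosity <= `max_het` (all comparisons inclusive). Locus order and
#' names are preserved. The package default mirrors the within-population
#' mapping filter (>= 50% completeness, MAF >= 35%, heterozygosity <= 8%).
#'
#' @param G genotype matrix.
#' @param min_completeness,min_maf,max_het thresholds in [0, 1].
#' @return filtered genotype matrix.
#' @export
filter_loci <- function(G, min_completeness = 0.5, min_maf = 0.35,
                        max_het = 0.08) {
  th <- c(min_completeness, min_maf, max_het)
  if (any(th < 0 | th > 1)) stop("thresholds must be in [0, 1]")
  st <- locus_stats(G)
  keep <- st$completeness >= min_completeness &
    !is.na(st$maf) & st$maf >= min_maf &
    !is.na(st$het) & st$het <= max_het
  G[, keep, drop = FALSE]
}

#' Per-sample depth index
#'
#' One unit of depth index corresponds to 2e6 good barcoded 100 bp reads per
#' DNA sample (the average share of a standard 95-plex lane); e.g. 1.16e6
#' reads give an index of 0.58.
#'
#' @param good_reads numeric vector of good barcoded read counts per sample.
#' @return data frame with good_reads and depth_index.
#' @export
depth_index <- function(good_reads) {
  if (any(good_reads < 0)) stop("read counts must be >= 0")
  data.frame(good_reads = good_reads, depth_index = good_reads / 2e6)
}

#' Sequencing-depth experiment
#'
#' For each depth level, simulates tag reads over the true genotypes, calls
#' genotypes, and counts loci passing the completeness thresholds (with
#' constant MAF and heterozygosity filters), mirroring the design of a
#' depth-titration experiment on a mapping population.
#'
#' @param G_truth true genotype matrix.
#' @param depth_levels increasing depth indices.
#' @param completeness_levels completeness thresholds (e.g. 0.25..0.90).
#' @param cfg a [sim_config()].
#' @param min_maf,max_het constant filters applied at each level.
#' @param stream substream shift for the read simulation.
#' @return data frame (depth_index, completeness, snp_count).
#' @export
depth_experiment <- function(G_truth, depth_levels,
                             completeness_levels = c(0.25, 0.5, 0.75, 0.9),
                             cfg = sim_config(), min_maf = 0.30,
                             max_het = 0.10, stream = 0L) {
  if (is.unsorted(depth_levels) || is.unsorted(completeness_levels))
    stop("levels must be sorted increasing")
  out <- list()
  for (d in depth_levels) {
    cfg_d <- cfg; cfg_d$depth_index <- d
    G <- call_genotypes(simulate_tag_reads(G_truth, cfg_d, stream = stream))
    for (cl in completeness_levels) {
      n <- ncol(filter_loci(G, min_completeness = cl, min_maf = min_maf,
                            max_het = max_het))
      out[[length(out) + 1]] <- data.frame(depth_index = d, completeness = cl,
                                           snp_count = n)
    }
  }
  do.call(rbind, out)
}

#' Sample-size experiment
#'
#' For each panel size, draws `replicates` random subsets of lines without
#' replacement, applies the filters, and counts loci passing each
#' completeness threshold — the design used to show that SNP counts plateau
#' as panel size grows.
#'
#' @param G genotype matrix for the full panel.
#' @param sizes panel sizes (each <= number of lines).
#' @param replicates random subsets per size.
#' @param completeness_levels completeness thresholds.
#' @param min_maf,max_het constant filters.
#' @param seed base seed for the subset draws.
#' @return data frame (n, completeness, replicate, snp_count).
#' @export
samplesize_experiment <- function(G, sizes, replicates = 2,
                                  completeness_levels = c(0.25, 0.5, 0.75, 0.9),
                                  min_maf = 0.05, max_het = 0.10, seed = 1L) {
  if (any(sizes > nrow(G))) stop("size exceeds available lines")
  out <- list()
  for (s in sizes) for (r in seq_len(replicates)) {
    set.seed(seed + 7919L * r + s)
    sub <- G[sample.int(nrow(G), s), , drop = FALSE]
    for (cl in completeness_levels) {
      n <- ncol(filter_loci(sub, min_completeness = cl, min_maf = min_maf,
                            max_het = max_het))
      out[[length(out) + 1]] <- data.frame(n = s, completeness = cl,
                                           replicate = r, snp_count = n)
    }
  }
  do.call(rbind, out)
}
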