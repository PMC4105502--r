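# Synthetic GBS data generator: genetic maps, RIL populations derived by
# repeated selfing, diversity panels with family structure, and a
# sequencing-depth model for tag-level read counts.

#' Simulation configuration
#'
#' Holds the study conditions the generator emulates: a 21-linkage-group
#' consensus map, six RIL populations of 52-145 F4-F8 lines with residual
#' heterozygosity, and a per-sample sequencing-depth model in which a depth
#' index of 1 corresponds to 2e6 good barcoded reads per sample.
#'
#' @param n_linkage_groups number of linkage groups.
#' @param lg_length linkage-group length in cM.
#' @param n_framework_loci framework loci per linkage group.
#' @param n_candidate_loci candidate (to-be-placed) loci per linkage group.
#' @param population_sizes RIL population sizes (lines per population).
#' @param generation filial generation k of an F_k RIL population.
#' @param outcross_rate probability per line per generation that a selfing is
#'   replaced by an outcross to a random line of the same population.
#' @param seq_error_rate per-read probability that a read is attributed to
#'   the wrong tag of its pair.
#' @param depth_index per-sample good reads divided by 2e6.
#' @param reads_per_locus_unit mean reads per line and locus at depth index
#'   1; controls how missingness scales with depth.
#' @param rng_seed integer seed; every simulator derives its stream from it.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_linkage_groups = 21, lg_length = 100,
                       n_framework_loci = 20, n_candidate_loci = 30,
                       population_sizes = c(98, 98, 53, 52, 53, 52),
                       generation = 6, outcross_rate = 0.01,
                       seq_error_rate = 0.002, depth_index = 1,
                       reads_per_locus_unit = 3, rng_seed = 1L) {
  probs <- c(outcross_rate, seq_error_rate)
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0, 1]")
  if (generation < 2) stop("generation must be >= 2 (an F1 segregates fully)")
  if (lg_length <= 0) stop("lg_length must be positive")
  if (n_linkage_groups < 1 || n_framework_loci < 1)
    stop("counts must be positive")
  if (depth_index < 0) stop("depth_index must be >= 0")
  structure(list(
    n_linkage_groups = as.integer(n_linkage_groups), lg_length = lg_length,
    n_framework_loci = as.integer(n_framework_loci),
    n_candidate_loci = as.integer(n_candidate_loci),
    population_sizes = as.integer(population_sizes),
    generation = as.integer(generation), outcross_rate = outcross_rate,
    seq_error_rate = seq_error_rate, depth_index = depth_index,
    reads_per_locus_unit = reads_per_locus_unit,
    rng_seed = as.integer(rng_seed)), class = "sim_config")
}

# Fixed stream offsets keep the simulators reproducible yet decorrelated
# under one global seed; `stream` shifts further for replicates.
.sim_seed <- function(cfg, base, stream = 0L) {
  set.seed((cfg$rng_seed + base + 1000L * stream) %% 2147483587L)
}

#' Haldane map-function conversions
#'
#' `haldane_r` converts a cM distance to a recombination fraction under the
#' no-interference (Haldane) model; `haldane_cm` is its inverse.
#'
#' @param d distance in cM.
#' @param r recombination fraction in [0, 0.5).
#' @export
haldane_r <- function(d) 0.5 * (1 - exp(-d / 50))

#' @rdname haldane_r
#' @export
haldane_cm <- function(r) {
  if (any(r >= 0.5)) stop("haldane_cm undefined for r >= 0.5")
  -50 * log(1 - 2 * r)
}

#' Simulate a consensus genetic map
#'
#' Framework loci are evenly spaced with jitter within each linkage group;
#' candidate loci fall uniformly at random. Positions are in cM, ascending
#' within each group.
#'
#' @param cfg a [sim_config()].
#' @return data frame with columns locus, linkage_group, position_cM, status
#'   (framework/candidate).
#' @export
simulate_consensus_map <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  .sim_seed(cfg, 0L)
  out <- vector("list", cfg$n_linkage_groups)
  for (g in seq_len(cfg$n_linkage_groups)) {
    nf <- cfg$n_framework_loci; nc <- cfg$n_candidate_loci
    fpos <- seq(0, cfg$lg_length, length.out = nf)
    if (nf > 2) {
      jit <- cfg$lg_length / (nf - 1) / 4
      fpos[-c(1, nf)] <- fpos[-c(1, nf)] + stats::runif(nf - 2, -jit, jit)
    }
    fpos <- sort(fpos)
    cpos <- sort(stats::runif(nc, 0, cfg$lg_length))
    lg <- sprintf("LG%02d", g)
    fr <- data.frame(locus = sprintf("%s_F%03d", lg, seq_len(nf)),
                     linkage_group = lg, position_cM = fpos,
                     status = "framework")
    ca <- if (nc > 0)
      data.frame(locus = sprintf("%s_C%03d", lg, seq_len(nc)),
                 linkage_group = lg, position_cM = cpos,
                 status = "candidate") else NULL
    piece <- rbind(fr, ca)
    out[[g]] <- piece[order(piece$position_cM, piece$locus), ]
  }
  map <- do.call(rbind, out)
  rownames(map) <- NULL
  map
}

# Per-locus crossover probabilities for one meiosis, loci in map order.
# The first locus of each chromosome gets r = 0.5 (independent start phase).
.meiosis_rvec <- function(map) {
  ord <- order(map$linkage_group, map$position_cM)
  stopifnot(identical(ord, seq_len(nrow(map))))
  r <- numeric(nrow(map))
  for (lg in unique(map$linkage_group)) {
    idx <- which(map$linkage_group == lg)
    r[idx[1]] <- 0.5
    if (length(idx) > 1)
      r[idx[-1]] <- haldane_r(diff(map$position_cM[idx]))
  }
  r
}

# One gamete per line from haplotype matrices hapA/hapB (n x L in {0,1}).
.gamete <- function(hapA, hapB, rvec) {
  n <- nrow(hapA); L <- ncol(hapA)
  phase <- matrix(0L, n, L)
  state <- integer(n)
  for (j in seq_len(L)) {
    state <- (state + stats::rbinom(n, 1L, rvec[j])) %% 2L
    phase[, j] <- state
  }
  ifelse(phase == 0L, hapA, hapB)
}

.haps_to_geno <- function(hapA, hapB, lines, loci) {
  s <- hapA + hapB
  G <- matrix("H", nrow(hapA), ncol(hapA), dimnames = list(lines, loci))
  G[s == 0L] <- "A"
  G[s == 2L] <- "B"
  G
}

#' Simulate a RIL population by repeated selfing
#'
#' Starts from an F1 heterozygous at every locus and selfs to generation
#' `generation`, drawing crossovers per interval under the Haldane
#' (no-interference) model per meiosis. Residual heterozygosity at F_k is
#' (1/2)^(k-1) in expectation before sequencing error. At rate
#' `cfg$outcross_rate` per line per generation one selfing gamete is replaced
#' by a gamete from a random other line of the population.
#'
#' @param map genetic map data frame, loci ordered within linkage groups.
#' @param n_lines number of RIL lines.
#' @param generation filial generation k (>= 2).
#' @param cfg a [sim_config()].
#' @param stream integer substream shift for replicate populations.
#' @return list with `genotypes` (A/B/H matrix, lines x loci) and `truth`
#'   (true map, per-locus phase labels, error-free genotypes).
#' @export
simulate_ril_population <- function(map, n_lines, generation = cfg$generation,
                                    cfg = sim_config(), stream = 0L) {
  if (generation < 2) stop("generation must be >= 2")
  if (nrow(map) == 0) stop("map is empty")
  .sim_seed(cfg, 1L, stream)
  map <- map[order(map$linkage_group, map$position_cM), ]
  rvec <- .meiosis_rvec(map)
  L <- nrow(map)
  hapA <- matrix(0L, n_lines, L)   # F1: one parental haplotype each
  hapB <- matrix(1L, n_lines, L)
  for (g in seq_len(generation - 1L)) {
    g1 <- .gamete(hapA, hapB, rvec)
    g2 <- .gamete(hapA, hapB, rvec)
    oc <- stats::runif(n_lines) < cfg$outcross_rate
    if (any(oc) && n_lines > 1) {
      donor <- vapply(which(oc), function(i)
        sample(setdiff(seq_len(n_lines), i), 1L), 1L)
      gd <- .gamete(hapA[donor, , drop = FALSE], hapB[donor, , drop = FALSE],
                    rvec)
      g2[oc, ] <- gd
    }
    hapA <- g1; hapB <- g2
  }
  lines <- sprintf("L%03d", seq_len(n_lines))
  G <- .haps_to_geno(hapA, hapB, lines, map$locus)
  truth <- list(true_map = map,
                true_phases = stats::setNames(rep("parent1", L), map$locus),
                true_kinship = NULL, true_genotypes = G)
  list(genotypes = G, truth = truth)
}

#' Simulate a diversity panel with family structure
#'
#' Inbred founders are drawn with random allele frequencies; each family
#' descends from an F1 between two founders sampled from a shared founder
#' pool and is selfed for four generations with recombination, so lines
#' within a family are closely related, families sharing a founder are
#' intermediate, and unrelated families are near zero - a coancestry
#' gradient without strong discrete structure. Expected (pedigree) kinship
#' is recorded as truth.
#'
#' @param n_families number of families.
#' @param lines_per_family lines per family.
#' @param cfg a [sim_config()].
#' @param map optional map (defaults to [simulate_consensus_map()]).
#' @param n_founders founder pool size (default `max(2, n_families)`).
#' @param stream integer substream shift.
#' @return list with `genotypes` and `truth` (incl. `true_kinship`).
#' @export
simulate_diversity_panel <- function(n_families, lines_per_family,
                                     cfg = sim_config(), map = NULL,
                                     n_founders = max(2L, n_families),
                                     stream = 0L) {
  if (n_families < 1 || lines_per_family < 1) stop("counts must be >= 1")
  if (is.null(map)) map <- simulate_consensus_map(cfg)
  .sim_seed(cfg, 2L, stream)
  map <- map[order(map$linkage_group, map$position_cM), ]
  L <- nrow(map)
  rvec <- .meiosis_rvec(map)
  # U-shaped founder allele-frequency spectrum: most variants rare, as in
  # real germplasm collections
  p <- 0.02 + 0.96 * stats::rbeta(L, 0.5, 0.5)
  founders <- matrix(stats::rbinom(n_founders * L, 1L, rep(p, each = n_founders)),
                     n_founders, L)
  fam_founders <- t(vapply(seq_len(n_families), function(f)
    sample.int(n_founders, 2L), integer(2)))
  n <- n_families * lines_per_family
  hapA <- matrix(0L, n, L); hapB <- matrix(0L, n, L)
  fam_of <- rep(seq_len(n_families), each = lines_per_family)
  for (f in seq_len(n_families)) {
    idx <- which(fam_of == f)
    hapA[idx, ] <- matrix(founders[fam_founders[f, 1], ], length(idx), L,
                          byrow = TRUE)
    hapB[idx, ] <- matrix(founders[fam_founders[f, 2], ], length(idx), L,
                          byrow = TRUE)
  }
  for (g in seq_len(4L)) {                    # selfing from the family F1s
    g1 <- .gamete(hapA, hapB, rvec)
    g2 <- .gamete(hapA, hapB, rvec)
    hapA <- g1; hapB <- g2
  }
  lines <- sprintf("P%03d", seq_len(n))
  G <- .haps_to_geno(hapA, hapB, lines, map$locus)
  kin <- matrix(0, n, n, dimnames = list(lines, lines))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    fi <- fam_founders[fam_of[i], ]; fj <- fam_founders[fam_of[j], ]
    kin[i, j] <- 0.25 * sum(outer(fi, fj, "=="))
  }
  diag(kin) <- 1
  truth <- list(true_map = map, true_phases = NULL, true_kinship = kin,
                true_genotypes = G, founder_freq = p, family = fam_of)
  list(genotypes = G, truth = truth)
}

#' Simulate tag-level read counts from true genotypes
#'
#' Per line and locus the total read count is Poisson with mean
#' `depth_index * reads_per_locus_unit`; reads are attributed to the line's
#' true allele tag(s) and flipped to the paired tag with probability
#' `seq_error_rate`. Zero total reads yield a missing call downstream.
#'
#' @param G true genotype matrix (A/B/H).
#' @param cfg a [sim_config()]; `cfg$depth_index` sets coverage.
#' @param stream integer substream shift.
#' @return a `tag_catalog` (see [tag_catalog()]).
#' @export
simulate_tag_reads <- function(G, cfg = sim_config(), stream = 0L) {
  if (cfg$depth_index < 0) stop("depth_index must be >= 0")
  .sim_seed(cfg, 3L, stream)
  n <- nrow(G); L <- ncol(G)
  bases <- c("A", "C", "G", "T")
  tagseq1 <- tagseq2 <- character(L)
  offs <- sample.int(64L, L, replace = TRUE) - 1L
  al1 <- al2 <- character(L)
  for (l in seq_len(L)) {
    s <- sample(bases, 64, replace = TRUE)
    a <- sample(bases, 2)
    s[offs[l] + 1] <- a[1]
    s2 <- s; s2[offs[l] + 1] <- a[2]
    tagseq1[l] <- paste(s, collapse = ""); tagseq2[l] <- paste(s2, collapse = "")
    al1[l] <- a[1]; al2[l] <- a[2]
  }
  lam <- cfg$depth_index * cfg$reads_per_locus_unit
  tot <- matrix(stats::rpois(n * L, lam), n, L)
  f <- matrix(0, n, L)                         # true fraction of tag-2 reads
  f[G == "B"] <- 1; f[G == "H"] <- 0.5
  p2 <- f * (1 - cfg$seq_error_rate) + (1 - f) * cfg$seq_error_rate
  c2 <- matrix(stats::rbinom(n * L, as.vector(tot), as.vector(p2)), n, L)
  c1 <- tot - c2
  counts <- matrix(0L, n, 2L * L)
  counts[, seq(1, 2 * L, 2)] <- c1
  counts[, seq(2, 2 * L, 2)] <- c2
  tag_names <- as.vector(rbind(paste0(colnames(G), "_t1"),
                               paste0(colnames(G), "_t2")))
  dimnames(counts) <- list(rownames(G), tag_names)
  tags <- stats::setNames(as.vector(rbind(tagseq1, tagseq2)), tag_names)
  pairs <- data.frame(locus = colnames(G),
                      tag_i = paste0(colnames(G), "_t1"),
                      tag_j = paste0(colnames(G), "_t2"),
                      snp_offset = offs, allele_i = al1, allele_j = al2,
                      stringsAsFactors = FALSE)
  tag_catalog(tags, counts, pairs)
}
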