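make_catalog <- function(seqs, counts_per_tag) {
  tags <- setNames(seqs, sprintf("t%02d", seq_along(seqs)))
  counts <- matrix(rep(counts_per_tag, each = 2), 2, length(tags),
                   dimnames = list(c("L01", "L02"), names(tags)))
  tag_catalog(tags, counts)
}

mutate_at <- function(s, pos, base) {
  substr(s, pos, pos) <- base
  s
}

base_tag <- strrep("ACGT", 16)

test_that("reciprocal tag pairs become candidate SNPs; complex families are dropped", {
  t2 <- mutate_at(base_tag, 7, "T")       # one mismatch at offset 6 (0-based)
  cat2 <- make_catalog(c(base_tag, t2), c(6, 6))  # 12 reads per tag
  snps <- pair_tags(cat2, max_mismatch = 1, min_tag_count = 10)
  expect_equal(nrow(snps), 1)
  expect_equal(snps$snp_offset, 6L)
  expect_equal(snps$alleles, "G/T")
  expect_match(snps$context, "\\[G/T\\]")

  # three mutually linked tags form a >2-member network: all discarded
  t3 <- mutate_at(base_tag, 7, "C")
  cat3 <- make_catalog(c(base_tag, t2, t3), c(6, 6, 6))
  expect_equal(nrow(pair_tags(cat3)), 0)

  # two mismatches exceed max_mismatch = 1: no pair
  t2b <- mutate_at(mutate_at(base_tag, 7, "T"), 20, "A")
  expect_equal(nrow(pair_tags(make_catalog(c(base_tag, t2b), c(6, 6)),
                              max_mismatch = 1)), 0)

  # low-coverage tags never enter pairing
  expect_equal(nrow(pair_tags(make_catalog(c(base_tag, t2), c(4, 6)))), 0)
})

test_that("Fisher population filter matches hypergeometric enumeration", {
  presence_from <- function(both, t1, t2, neither) {
    cbind(rep(c(TRUE, TRUE, FALSE, FALSE), c(both, t1, t2, neither)),
          rep(c(TRUE, FALSE, TRUE, FALSE), c(both, t1, t2, neither)))
  }
  # perfectly complementary tags in 20 lines: p = 2/choose(20,10)
  res <- fisher_population_filter(presence_from(0, 10, 10, 0))
  expect_equal(res$p_value, 2 / choose(20, 10), tolerance = 1e-12)
  expect_equal(res$p_value, fisher_enum_p(0, 10, 10, 0), tolerance = 1e-12)
  expect_true(res$accepted)

  # perfect independence: p = 1, rejected
  res <- fisher_population_filter(presence_from(5, 5, 5, 5))
  expect_equal(res$p_value, 1)
  expect_false(res$accepted)

  # weak association rejected at alpha = 0.001
  res <- fisher_population_filter(presence_from(2, 8, 8, 2))
  expect_equal(res$p_value, fisher_enum_p(2, 8, 8, 2), tolerance = 1e-12)
  expect_gt(res$p_value, 0.001)
  expect_false(res$accepted)

  # zero margin: p = 1, rejected
  res <- fisher_population_filter(presence_from(0, 0, 6, 4))
  expect_equal(res$p_value, 1)
  expect_error(fisher_population_filter(presence_from(0, 0, 0, 0)), "empty|2 lines")
})

test_that("allelic tag pairs in an inbred population pass the filter with power", {
  set.seed(21)
  n <- 60; accept <- logical(200)
  for (i in seq_len(200)) {
    g <- rbinom(n, 1, 0.5)                       # inbred biallelic locus
    covered <- rbinom(n, 1, 0.9) == 1            # 90% call rate
    pres <- cbind(g == 0 & covered, g == 1 & covered)
    accept[i] <- fisher_population_filter(pres)$accepted
  }
  expect_gte(mean(accept), 0.95)
})

test_that("genotype calls follow the error-tolerance rule and its boundary", {
  tags <- setNames(c(base_tag, mutate_at(base_tag, 3, "T")), c("a", "b"))
  counts <- matrix(c(5, 4, 99, 1,
                     0, 4, 1, 99), 4, 2,
                   dimnames = list(sprintf("L%02d", 1:4), names(tags)))
  cat <- tag_catalog(tags, counts,
                     pairs = data.frame(locus = "m1", tag_i = "a", tag_j = "b",
                                        snp_offset = 2L, allele_i = "G",
                                        allele_j = "T"))
  G <- call_genotypes(cat, error_tolerance = 0.02)
  expect_equal(unname(G[, "m1"]), c("A", "H", "A", "B"))
  # (5,0) hom, (4,4) het, (99,1): 1/100 at the tolerance -> hom (strict >)
  empty <- cat; empty$counts[] <- 0L
  expect_equal(unname(call_genotypes(empty)[, "m1"]), rep("N", 4))
})

test_that("calls on error-free fully covered data reproduce truth exactly", {
  cfg <- sim_config(n_linkage_groups = 1, n_framework_loci = 25,
                    n_candidate_loci = 0, seq_error_rate = 0,
                    depth_index = 40, rng_seed = 2)
  map <- simulate_consensus_map(cfg)
  pop <- simulate_ril_population(map, 30, 5, cfg)
  cat <- simulate_tag_reads(pop$genotypes, cfg)
  called <- call_genotypes(cat)
  covered <- called != "N"
  expect_gt(mean(covered), 0.999)
  expect_true(all(called[covered] == pop$genotypes[covered]))
})

test_that("tri- and tetra-allelic sets are detected from shared contexts", {
  ctx <- function(a1, a2) paste0(substr(base_tag, 1, 10), "[", a1, "/", a2, "]",
                                 substr(base_tag, 12, 64))
  snps <- data.frame(name = c("s1", "s2", "s3", "s4", "s5"),
                     context = c(ctx("A", "C"), ctx("A", "G"),   # tri {A,C,G}
                                 ctx("A", "C"),                  # duplicate of s1
                                 mutate_at(ctx("A", "C"), 1, "T"), # different context
                                 ctx("G", "T")),
                     alleles = c("A/C", "A/G", "A/C", "A/C", "G/T"),
                     stringsAsFactors = FALSE)
  res <- detect_multiallelic(snps[c(1, 2), ])
  expect_length(res$tri_sets, 1)
  expect_length(res$tetra_sets, 0)
  res4 <- detect_multiallelic(snps[c(1, 5), ])
  expect_length(res4$tetra_sets, 1)
  # duplicates and context mismatches yield no sets
  expect_length(detect_multiallelic(snps[c(1, 3), ])$tri_sets, 0)
  expect_length(detect_multiallelic(snps[c(1, 4), ])$tri_sets, 0)
})

test_that("catalog merging unifies by canonical context and is idempotent", {
  ctxA <- paste0(strrep("AC", 5), "[A/C]", strrep("GT", 26), "G")
  revc <- function(s) chartr("ACGT", "TGCA",
                             paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  parts <- strsplit(ctxA, "[][]")[[1]]
  ctxA_rev <- paste0(revc(parts[3]), "[G/T]", revc(parts[1]))
  a <- data.frame(name = "GBS000001", context = ctxA, alleles = "A/C",
                  snp_offset = 10L, p_value = 1e-5, source = "population",
                  stringsAsFactors = FALSE)
  b <- data.frame(name = c("u1", "u2"),
                  context = c(ctxA_rev, paste0(strrep("T", 20), "[A/G]",
                                               strrep("C", 43))),
                  alleles = c("G/T", "A/G"), snp_offset = c(53L, 20L),
                  p_value = c(2e-4, 3e-4), source = "pairwise",
                  stringsAsFactors = FALSE)
  m <- merge_catalogs(a, b)
  expect_equal(nrow(m), 2)                     # reverse strand unified
  expect_equal(m$source[m$name == "GBS000001"], "both")
  expect_equal(sort(m$name), c("GBS000001", "GBS000002"))
  expect_identical(merge_catalogs(m, b)$name, m$name)
  bad <- a; bad$name <- "u1"
  bad$context <- paste0(strrep("G", 20), "[A/C]", strrep("T", 43))
  expect_error(merge_catalogs(bad, b), "differing context")
})
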