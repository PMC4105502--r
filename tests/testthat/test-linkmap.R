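test_that("recombination fractions by simple recombinant counting", {
  # identical columns -> r = 0; complementary coding -> apparent r = 1
  G <- geno_from("AA", "AA", "BB", "BB")
  expect_equal(estimate_rf(G, 1, 2)$r, 0)
  Gc <- geno_from("AB", "AB", "BA", "BA")
  expect_equal(estimate_rf(Gc, 1, 2)$r, 1)

  # 10 recombinants of 50 informative lines -> r = 0.2; hets excluded
  calls1 <- c(rep("A", 25), rep("B", 25), rep("H", 5))
  calls2 <- c(rep("A", 20), rep("B", 5), rep("B", 20), rep("A", 5), rep("A", 5))
  G2 <- cbind(m1 = calls1, m2 = calls2)
  rownames(G2) <- sprintf("L%02d", 1:55)
  res <- estimate_rf(G2, "m1", "m2")
  expect_equal(res$n_informative, 50L)
  expect_equal(res$r, 0.2)

  # matrix form agrees with brute-force pair counting
  set.seed(8)
  Gr <- matrix(sample(c("A", "B", "H", "N"), 20 * 6, replace = TRUE), 20, 6,
               dimnames = list(sprintf("L%02d", 1:20), sprintf("m%d", 1:6)))
  rf <- rf_matrix(Gr)
  for (i in 1:5) for (j in (i + 1):6) {
    brute <- estimate_rf(Gr, i, j)
    expect_equal(rf$r[i, j], brute$r)
    expect_equal(rf$n[i, j], brute$n_informative)
  }
  expect_true(isSymmetric(rf$r) || all(is.na(rf$r[is.na(t(rf$r))])))
  expect_equal(unname(diag(rf$r)), rep(0, 6))
})

test_that("parental phase assignment orients or duplicates loci", {
  progeny <- geno_from("ABH", "BAN", "AAB")
  parents <- geno_from("BAA", "ABA", lines = c("P1", "P2"),
                       loci = colnames(progeny))
  # m1: parents B/A -> progeny flipped; m2: A/B kept; m3: monomorphic -> twins
  res <- assign_phase(progeny, parents)
  expect_equal(unname(res$genotypes[, "M01"]), c("B", "A", "B"))
  expect_equal(unname(res$genotypes[, "M02"]), c("B", "A", "A"))
  expect_true(all(c("M03_p1", "M03_p2") %in% colnames(res$genotypes)))
  expect_equal(unname(res$genotypes[, "M03_p1"]), c("H", "N", "B"))
  expect_equal(unname(res$genotypes[, "M03_p2"]), c("H", "N", "A"))
  # no parents at all: everything duplicated
  res2 <- assign_phase(progeny, NULL)
  expect_equal(ncol(res2$genotypes), 6)
  expect_true(all(res2$report$parental_status == "uninformative"))
})

test_that("phase correction flips a planted out-of-phase locus and keeps isolates", {
  cfg <- sim_config(n_linkage_groups = 1, n_framework_loci = 6, lg_length = 10,
                    n_candidate_loci = 0, outcross_rate = 0, rng_seed = 17)
  map <- simulate_consensus_map(cfg)
  G <- simulate_ril_population(map, 80, 6, cfg)$genotypes
  Gf <- G
  Gf[, 3] <- flip_calls(Gf[, 3])
  res <- correct_phases(Gf)
  expect_equal(res$report$action[3], "flipped")
  expect_equal(res$report$iteration[3], 1L)
  expect_identical(res$genotypes, G)

  # an unlinked locus (in = out = 0) is kept unchanged
  iso <- cbind(G, iso = sample(c("A", "B"), 80, replace = TRUE))
  res2 <- correct_phases(iso)
  expect_equal(res2$report$action[res2$report$locus == "iso"], "kept")
  expect_true("iso" %in% colnames(res2$genotypes))
})

test_that("exactly one of each both-phase twin pair survives phase checking", {
  cfg <- sim_config(n_linkage_groups = 1, n_framework_loci = 8, lg_length = 15,
                    n_candidate_loci = 0, outcross_rate = 0, rng_seed = 23)
  map <- simulate_consensus_map(cfg)
  G <- simulate_ril_population(map, 80, 6, cfg)$genotypes
  phased <- assign_phase(G, NULL)   # every locus duplicated in both phases
  res <- correct_phases(phased$genotypes)
  base <- sub("_p[12]$", "", colnames(res$genotypes))
  expect_equal(sort(unique(base)), sort(colnames(G)))
  expect_equal(anyDuplicated(base), 0)
})

test_that("marker placement interpolates between the two closest anchors", {
  fw <- data.frame(locus = c("f1", "f2", "f3"), linkage_group = "LG01",
                   position_cM = c(0, 10, 30), status = "framework")
  mk_rf <- function(r_cand, r_f) {
    loci <- c("cand", "f1", "f2", "f3")
    r <- matrix(NA_real_, 4, 4, dimnames = list(loci, loci))
    diag(r) <- 0
    r["cand", c("f1", "f2", "f3")] <- r[c("f1", "f2", "f3"), "cand"] <- r_cand
    r["f1", "f2"] <- r["f2", "f1"] <- r_f[1]
    r["f2", "f3"] <- r["f3", "f2"] <- r_f[2]
    r["f1", "f3"] <- r["f3", "f1"] <- min(0.49, r_f[1] + r_f[2])
    n <- matrix(100L, 4, 4, dimnames = list(loci, loci))
    list(r = r, n = n)
  }
  # interior anchors 10 and 30 cM, rf 0.05 / 0.15 -> 10 + 20 * 0.25 = 15 cM
  rf <- mk_rf(c(0.40, 0.05, 0.15), c(0.09, 0.17))
  res <- place_markers(fw, "cand", list(pop1 = rf))
  expect_equal(res$map$position_cM[res$map$locus == "cand"], 15)
  expect_equal(res$map$anchor1[res$map$locus == "cand"], "f2")

  # rf(c, f1) = 0 -> placed exactly on f1
  rf0 <- mk_rf(c(0.35, 0, 0.12), c(0.09, 0.17))
  res0 <- place_markers(fw, "cand", list(pop1 = rf0))
  expect_equal(res0$map$position_cM[res0$map$locus == "cand"], 10)

  # terminal anchor at 0 cM with rf(c,f2) > rf(f1,f2): distal at -100*rf
  rfd <- mk_rf(c(0.05, 0.25, 0.45), c(0.18, 0.2))
  resd <- place_markers(fw, "cand", list(pop1 = rfd))
  expect_equal(resd$map$position_cM[resd$map$locus == "cand"], -5)

  # candidate unlinked everywhere is reported unplaced
  rfu <- mk_rf(c(0.5, 0.5, 0.5), c(0.18, 0.2))
  resu <- place_markers(fw, "cand", list(pop1 = rfu))
  expect_equal(resu$unplaced, "cand")
})

test_that("anchors take the smallest rf across populations", {
  fw <- data.frame(locus = c("f1", "f2"), linkage_group = "LG01",
                   position_cM = c(10, 30), status = "framework")
  mk <- function(r1, r2) {
    loci <- c("cand", "f1", "f2")
    r <- matrix(0.45, 3, 3, dimnames = list(loci, loci)); diag(r) <- 0
    r["cand", "f1"] <- r["f1", "cand"] <- r1
    r["cand", "f2"] <- r["f2", "cand"] <- r2
    r["f1", "f2"] <- r["f2", "f1"] <- 0.2
    list(r = r, n = matrix(80L, 3, 3, dimnames = list(loci, loci)))
  }
  res <- place_markers(fw, "cand", list(popA = mk(0.3, 0.15),
                                        popB = mk(0.05, 0.45)))
  row <- res$map[res$map$locus == "cand", ]
  expect_equal(row$anchor1, "f1")
  expect_equal(row$rf1, 0.05)          # best rf over populations
  expect_equal(row$source_population, "popB")
  expect_equal(row$rf2, 0.15)          # f2's best is from popA
  expect_equal(row$position_cM, 10 + 20 * 0.05 / 0.20)
})

test_that("map density bins are half-open and conserve locus counts", {
  map <- data.frame(locus = c("a", "b", "c", "d"), linkage_group = "LG01",
                    position_cM = c(0, 4.9, 5.0, -0.1), status = "placed")
  h <- map_density(map, bin = 5)
  expect_equal(h$count[h$bin_start == 0], 2)
  expect_equal(h$count[h$bin_start == 5], 1)
  expect_equal(h$count[h$bin_start == -5], 1)   # negative positions binned
  expect_equal(sum(h$count), 4)
  expect_equal(nrow(map_density(map[0, ], 5)), 0)
})

test_that("gap statistics count intervals over the threshold", {
  map <- data.frame(locus = letters[1:3], linkage_group = "LG01",
                    position_cM = c(0, 8, 10), status = "framework")
  gs <- gap_stats(map, threshold = 5)
  expect_equal(gs$n_gaps_over_threshold, 1)
  expect_equal(gs$max_gap, 8)
  uni <- data.frame(locus = letters[1:5], linkage_group = "LG01",
                    position_cM = 0:4, status = "framework")
  expect_equal(gap_stats(uni, 5)$n_gaps_over_threshold, 0)
})

test_that("Kosambi and Haldane map functions match closed forms", {
  expect_equal(kosambi_cm(0), 0)
  expect_equal(kosambi_cm(0.2), 25 * log(1.4 / 0.6))
  expect_equal(round(kosambi_cm(0.2), 2), 21.18)
  expect_equal(round(kosambi_cm(0.25), 2), 27.47)
  expect_error(kosambi_cm(0.5), "r < 0.5")
  expect_equal(kosambi_r(kosambi_cm(0.3)), 0.3, tolerance = 1e-12)
  expect_equal(haldane_r(haldane_cm(0.23)), 0.23, tolerance = 1e-12)
})

test_that("de novo mapping recovers chromosomes and drops unlinked material", {
  cfg <- sim_config(n_linkage_groups = 2, n_framework_loci = 25, lg_length = 60,
                    n_candidate_loci = 0, outcross_rate = 0, rng_seed = 31)
  map <- simulate_consensus_map(cfg)
  G <- simulate_ril_population(map, 150, 6, cfg)$genotypes
  dn <- denovo_map(G)
  expect_equal(length(unique(dn$linkage_group)), 2)
  for (lg in unique(dn$linkage_group)) {
    sub <- dn[dn$linkage_group == lg, ]
    truth <- map[match(sub$locus, map$locus), ]
    expect_equal(length(unique(truth$linkage_group)), 1)
    # adjacent distances close to truth for the recovered order
    tru_pos <- truth$position_cM
    est_gap <- diff(sub$position_cM)
    tru_gap <- abs(diff(tru_pos))
    expect_lt(stats::median(abs(est_gap - tru_gap)), 3)
  }
  # a pair of tightly linked but otherwise isolated loci is excluded
  set.seed(5)
  g_iso <- sample(c("A", "B"), 150, TRUE)
  extra <- cbind(G, i1 = g_iso, i2 = g_iso)   # r(i1,i2) = 0, a two-locus group
  dn2 <- denovo_map(extra)
  expect_false(any(c("i1", "i2") %in% dn2$locus))
})
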