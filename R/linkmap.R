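# Linkage mapping: recombination-fraction estimation by simple recombinant
# counting, parental phase assignment and recursive correction, placement of
# candidate loci on a framework map by rf interpolation with a distal rule,
# map density and gap statistics, and de novo grouping/ordering with Kosambi
# distances.

#' Pairwise recombination fractions by simple recombinant counting
#'
#' Over lines with non-missing homozygous calls at both loci, the apparent
#' recombination fraction is the proportion of non-parental two-locus
#' genotypes. Heterozygous calls are excluded: RIL populations are
#' near-inbred and simple recombinant counting uses homozygotes only. Values
#' above 0.5 signal phase conflict (the complement of the true fraction).
#'
#' @param G phased genotype matrix (A/B/H/N).
#' @return list with `r` (locus x locus apparent rf, NA where no informative
#'   lines) and `n` (informative-line counts). Diagonal of `r` is 0.
#' @export
rf_matrix <- function(G) {
  A <- (G == "A") * 1; B <- (G == "B") * 1
  n_inf <- crossprod(A + B)
  rec <- crossprod(A, B) + crossprod(B, A)
  r <- ifelse(n_inf > 0, rec / n_inf, NA_real_)
  diag(r) <- 0
  dimnames(r) <- dimnames(n_inf) <- list(colnames(G), colnames(G))
  list(r = r, n = n_inf)
}

#' @rdname rf_matrix
#' @param i,j locus names or indices.
#' @return `estimate_rf` returns a list with `r` and `n_informative` for one
#'   pair.
#' @export
estimate_rf <- function(G, i, j) {
  x <- G[, i]; y <- G[, j]
  inf <- x %in% c("A", "B") & y %in% c("A", "B")
  n <- sum(inf)
  if (n == 0) return(list(r = NA_real_, n_informative = 0L))
  list(r = sum(x[inf] != y[inf]) / n, n_informative = n)
}

#' Assign parental phase to progeny calls
#'
#' Where both parents have homozygous, polymorphic calls, progeny calls are
#' oriented so "A" is the parent-1 allele. Loci with missing, heterozygous
#' or monomorphic parental calls are emitted in both phases under suffixed
#' names (`_p1` as scored, `_p2` complemented); the downstream phase check
#' keeps the right twin.
#'
#' @param progeny genotype matrix.
#' @param parents two-row genotype matrix for the parents, or NULL.
#' @return list with `genotypes` (phased, possibly widened) and `report`
#'   (locus, parental_status).
#' @export
assign_phase <- function(progeny, parents = NULL) {
  loci <- colnames(progeny)
  status <- rep("uninformative", length(loci))
  if (!is.null(parents)) {
    p1 <- parents[1, loci]; p2 <- parents[2, loci]
    ok <- p1 %in% c("A", "B") & p2 %in% c("A", "B") & p1 != p2
    status[ok] <- "oriented"
  } else ok <- rep(FALSE, length(loci))
  out <- vector("list", length(loci))
  for (k in seq_along(loci)) {
    x <- progeny[, k]
    if (ok[k]) {
      if (parents[1, loci[k]] == "B") x <- flip_calls(x)
      out[[k]] <- stats::setNames(data.frame(x), loci[k])
    } else {
      out[[k]] <- stats::setNames(data.frame(x, flip_calls(x)),
                                  paste0(loci[k], c("_p1", "_p2")))
    }
  }
  G <- as.matrix(do.call(cbind, out))
  rownames(G) <- rownames(progeny)
  list(genotypes = G,
       report = data.frame(locus = loci, parental_status = status))
}

#' Recursive phase correction
#'
#' For each locus, linked loci with apparent rf below `low` are counted as
#' in-phase and those above `high` as out-of-phase. A locus with more
#' out-of-phase than in-phase matches is rescored in the opposite phase
#' (calls complemented, its rf row becoming 1 - r); the census is repeated
#' until no locus flips. A locus that remains conflicted after flipping
#' (i.e. would flip back) is eliminated. Ties, including isolated loci with
#' no linked neighbours, are kept unchanged: flipping without evidence is
#' unjustified. Of a both-phase twin pair only one copy survives.
#'
#' @param G phased genotype matrix.
#' @param rf optional precomputed [rf_matrix()] of `G`.
#' @param low,high rf thresholds for in-/out-of-phase linkage.
#' @param max_iter iteration cap; loci still conflicted at the cap are
#'   eliminated with a warning.
#' @return list with `genotypes` (corrected matrix, eliminated loci removed)
#'   and `report` (locus, in_phase, out_phase, action, iteration).
#' @export
correct_phases <- function(G, rf = NULL, low = 0.20, high = 0.80,
                           max_iter = 10) {
  if (is.null(rf)) rf <- rf_matrix(G)
  r <- rf$r
  loci <- colnames(G)
  flips <- integer(length(loci)); names(flips) <- loci
  action <- stats::setNames(rep("kept", length(loci)), loci)
  iter_of <- stats::setNames(rep(0L, length(loci)), loci)
  in_out <- function(k) {
    row <- r[k, -k]
    c(sum(row < low, na.rm = TRUE), sum(row > high, na.rm = TRUE))
  }
  alive <- rep(TRUE, length(loci))
  for (it in seq_len(max_iter)) {
    changed <- FALSE
    for (k in which(alive)) {
      io <- in_out(k)
      if (io[2] > io[1]) {
        if (flips[k] >= 1L) {            # flipping back would not improve
          alive[k] <- FALSE
          action[loci[k]] <- "eliminated"; iter_of[loci[k]] <- it
          r[k, ] <- NA; r[, k] <- NA
        } else {
          flips[k] <- flips[k] + 1L
          G[, k] <- flip_calls(G[, k])
          keep <- seq_along(loci) != k
          r[k, keep] <- 1 - r[k, keep]
          r[keep, k] <- 1 - r[keep, k]
          action[loci[k]] <- "flipped"; iter_of[loci[k]] <- it
        }
        changed <- TRUE
      }
    }
    if (!changed) break
    if (it == max_iter) {
      bad <- which(alive & vapply(seq_along(loci), function(k) {
        io <- in_out(k); io[2] > io[1]
      }, TRUE))
      if (length(bad)) {
        warning("phase correction did not converge; eliminating ",
                length(bad), " conflicted loci")
        alive[bad] <- FALSE
        action[loci[bad]] <- "eliminated"; iter_of[loci[bad]] <- it
      }
    }
  }
  # Both-phase twins: after correction the surviving twins are redundant
  # complements/duplicates; keep the _p1 copy when both are still alive.
  twin_base <- sub("_p[12]$", "", loci)
  is_twin <- grepl("_p[12]$", loci)
  for (b in unique(twin_base[is_twin])) {
    idx <- which(twin_base == b & is_twin & alive)
    if (length(idx) > 1) {
      drop <- idx[order(loci[idx])][-1]
      alive[drop] <- FALSE
      action[loci[drop]] <- "eliminated"
    }
  }
  io_final <- t(vapply(seq_along(loci), in_out, numeric(2)))
  report <- data.frame(locus = loci, in_phase = io_final[, 1],
                       out_phase = io_final[, 2], action = unname(action),
                       iteration = unname(iter_of))
  list(genotypes = G[, alive, drop = FALSE], report = report)
}

#' Place candidate loci on a framework map
#'
#' Each candidate is anchored to the two framework loci with the smallest
#' apparent rf to it across all populations (ties broken by larger
#' informative-line count, then locus name). With anchors f1 (closest) and
#' f2: if f1 is interior to its linkage group, or rf(c, f2) <= rf(f1, f2),
#' the position is interpolated between the anchors proportionally to the
#' rf values; if f1 is terminal and rf(c, f2) > rf(f1, f2) the candidate is
#' placed distal to the end of the group at 1 cM per 1% rf beyond f1
#' (positions below 0 cM are therefore possible off the start of a group).
#'
#' @param framework map data frame of framework loci.
#' @param candidates character vector of candidate locus names.
#' @param rf_by_population named list of [rf_matrix()] results, one per
#'   population, each covering the loci it segregates.
#' @param max_rf candidates with no framework rf below this in any
#'   population are left unplaced.
#' @return list with `map` (framework plus placed loci with provenance
#'   columns anchor1, rf1, anchor2, rf2, source_population) and `unplaced`.
#' @export
place_markers <- function(framework, candidates, rf_by_population,
                          max_rf = 0.5) {
  stopifnot(nrow(framework) > 0)
  fw <- framework[order(framework$linkage_group, framework$position_cM), ]
  placed <- list(); unplaced <- character()
  for (cand in candidates) {
    best <- .best_anchors(cand, fw$locus, rf_by_population, max_rf)
    if (is.null(best)) { unplaced <- c(unplaced, cand); next }
    f1 <- best$locus[1]; rf1 <- best$r[1]
    i1 <- match(f1, fw$locus)
    lg <- fw$linkage_group[i1]
    # second anchor: next distinct framework locus by rf
    rest <- best[best$locus != f1, , drop = FALSE]
    if (!nrow(rest)) { unplaced <- c(unplaced, cand); next }
    f2 <- rest$locus[1]; rf2 <- rest$r[1]
    i2 <- match(f2, fw$locus)
    p1 <- fw$position_cM[i1]; p2 <- fw$position_cM[i2]
    grp <- fw[fw$linkage_group == lg, ]
    terminal <- p1 <= min(grp$position_cM) || p1 >= max(grp$position_cM)
    rf12 <- .pooled_min_rf(f1, f2, rf_by_population)
    if (!terminal || (!is.na(rf12) && rf2 <= rf12)) {
      pos <- if (rf1 + rf2 > 0) p1 + (p2 - p1) * rf1 / (rf1 + rf2) else p1
    } else {
      dir <- if (p1 <= min(grp$position_cM)) -1 else 1
      pos <- p1 + dir * 100 * rf1
    }
    placed[[length(placed) + 1]] <- data.frame(
      locus = cand, linkage_group = lg, position_cM = pos, status = "placed",
      anchor1 = f1, rf1 = rf1, anchor2 = f2, rf2 = rf2,
      source_population = best$population[1], stringsAsFactors = FALSE)
  }
  fw$anchor1 <- NA_character_; fw$rf1 <- NA_real_
  fw$anchor2 <- NA_character_; fw$rf2 <- NA_real_
  fw$source_population <- NA_character_
  map <- rbind(fw, do.call(rbind, placed))
  map <- map[order(map$linkage_group, map$position_cM, map$locus), ]
  rownames(map) <- NULL
  list(map = map, unplaced = unplaced)
}

# All (framework locus, rf, n, population) records for a candidate, sorted
# by rf, then informative count (desc), then locus name; best per locus.
.best_anchors <- function(cand, fw_loci, rf_by_population, max_rf) {
  recs <- list()
  for (pop in names(rf_by_population)) {
    rf <- rf_by_population[[pop]]
    if (!cand %in% rownames(rf$r)) next
    hits <- intersect(fw_loci, colnames(rf$r))
    r <- rf$r[cand, hits]; n <- rf$n[cand, hits]
    ok <- !is.na(r) & r < max_rf & n > 0
    if (any(ok))
      recs[[length(recs) + 1]] <- data.frame(
        locus = hits[ok], r = r[ok], n = n[ok], population = pop,
        stringsAsFactors = FALSE)
  }
  if (!length(recs)) return(NULL)
  recs <- do.call(rbind, recs)
  recs <- recs[order(recs$r, -recs$n, recs$locus), ]
  recs[!duplicated(recs$locus), ]
}

.pooled_min_rf <- function(f1, f2, rf_by_population) {
  vals <- vapply(rf_by_population, function(rf) {
    if (f1 %in% rownames(rf$r) && f2 %in% colnames(rf$r)) rf$r[f1, f2]
    else NA_real_
  }, 0)
  if (all(is.na(vals))) NA_real_ else min(vals, na.rm = TRUE)
}

#' Marker density histogram in fixed cM bins
#'
#' Counts placed loci per half-open bin `[k*bin, (k+1)*bin)`; negative
#' (distal) positions fall in negative-index bins.
#'
#' @param map map data frame.
#' @param bin bin width in cM.
#' @param status which loci to count (default placed only).
#' @return data frame (linkage_group, bin_start, count).
#' @export
map_density <- function(map, bin = 5, status = "placed") {
  m <- map[map$status %in% status, ]
  if (!nrow(m)) return(data.frame(linkage_group = character(),
                                  bin_start = numeric(), count = integer()))
  b <- floor(m$position_cM / bin) * bin
  agg <- stats::aggregate(list(count = b),
                          by = list(linkage_group = m$linkage_group,
                                    bin_start = b), FUN = length)
  agg[order(agg$linkage_group, agg$bin_start), ]
}

#' Gap statistics of a genetic map
#'
#' Computes adjacent-interval lengths within each linkage group, the number
#' of intervals exceeding `threshold`, and the largest interval.
#'
#' @param map map data frame (>= 2 loci per counted group).
#' @param threshold gap threshold in cM.
#' @return list with `n_gaps_over_threshold`, `max_gap`, and `intervals`.
#' @export
gap_stats <- function(map, threshold = 5) {
  gaps <- unlist(lapply(split(map$position_cM, map$linkage_group),
                        function(p) if (length(p) >= 2) diff(sort(p)) else numeric()))
  list(n_gaps_over_threshold = sum(gaps > threshold),
       max_gap = if (length(gaps)) max(gaps) else NA_real_,
       intervals = gaps)
}

#' Kosambi map function
#'
#' `kosambi_cm` converts a recombination fraction to a Kosambi map distance
#' d = 25 ln((1+2r)/(1-2r)) cM; `kosambi_r` is the inverse.
#'
#' @param r recombination fraction in [0, 0.5).
#' @param d distance in cM.
#' @export
kosambi_cm <- function(r) {
  if (any(r >= 0.5 | r < 0)) stop("kosambi_cm defined for 0 <= r < 0.5")
  25 * log((1 + 2 * r) / (1 - 2 * r))
}

#' @rdname kosambi_cm
#' @export
kosambi_r <- function(d) 0.5 * tanh(d / 50)

#' De novo linkage map
#'
#' Linkage groups are connected components of the graph joining locus pairs
#' with apparent rf below `link_threshold_r`. Loci farther than `max_distal`
#' (Kosambi cM) from every other locus are excluded as unlinked, as are
#' groups with fewer than `min_group` loci. Within a group, loci are ordered
#' along the minimum-spanning tree of rf distances (depth-first from one end
#' of the tree diameter — a simple documented heuristic, not a full ordering
#' algorithm); adjacent map distances are Kosambi-transformed rf re-estimated
#' from the data for the final order.
#'
#' @param G phased, filtered genotype matrix.
#' @param link_threshold_r rf threshold for linkage-group membership.
#' @param min_group minimum loci per retained group.
#' @param max_distal exclusion distance in cM for unlinked loci.
#' @return map data frame (locus, linkage_group, position_cM, status).
#' @export
denovo_map <- function(G, link_threshold_r = 0.25, min_group = 3,
                       max_distal = 15) {
  rf <- rf_matrix(G)
  r <- rf$r
  loci <- colnames(G)
  rmax <- kosambi_r(max_distal)
  rr <- r; diag(rr) <- NA
  linked <- apply(rr, 1, function(x) any(!is.na(x) & x < rmax))
  keep <- which(linked)
  if (!length(keep)) return(.empty_map())
  r <- r[keep, keep, drop = FALSE]; loci <- loci[keep]
  adj <- !is.na(r) & r < link_threshold_r
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)
  out <- list(); lg_i <- 0L
  for (k in order(-comp$csize)) {
    members <- which(comp$membership == k)
    if (length(members) < min_group) next
    lg_i <- lg_i + 1L
    ord <- .mst_order(r[members, members, drop = FALSE])
    ml <- loci[members][ord]
    radj <- r[cbind(match(ml[-length(ml)], loci), match(ml[-1], loci))]
    radj <- pmin(radj, 0.499)
    pos <- c(0, cumsum(kosambi_cm(radj)))
    out[[lg_i]] <- data.frame(locus = ml,
                              linkage_group = sprintf("DN%02d", lg_i),
                              position_cM = pos, status = "framework",
                              stringsAsFactors = FALSE)
  }
  if (!length(out)) return(.empty_map())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

.empty_map <- function() {
  data.frame(locus = character(), linkage_group = character(),
             position_cM = numeric(), status = character())
}

# Order loci along the MST of rf distances: depth-first traversal rooted at
# one endpoint of the tree diameter.
.mst_order <- function(r) {
  n <- nrow(r)
  if (n == 1) return(1L)
  w <- r; w[is.na(w)] <- 0.5
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  t <- igraph::mst(g)
  dia <- igraph::get_diameter(t)
  root <- as.integer(dia[1])
  as.integer(igraph::dfs(t, root = root)$order)
}
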