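# Genotype calls are stored as a character matrix, lines in rows, loci in
# columns, coded A / B / H / N (hom first allele, hom second allele,
# heterozygous, missing).  Phased matrices orient "A" to parent 1.

GENO_CODES <- c("A", "B", "H", "N")

#' Validate a genotype matrix
#'
#' Checks that `G` is a character matrix with calls coded A/B/H/N and with
#' line (row) and locus (column) names.
#'
#' @param G candidate genotype matrix.
#' @return `G` invisibly; stops with an informative error otherwise.
#' @export
validate_genotype_matrix <- function(G) {
  if (!is.matrix(G) || !is.character(G))
    stop("genotype matrix must be a character matrix")
  if (is.null(rownames(G)) || is.null(colnames(G)))
    stop("genotype matrix must have line (row) and locus (column) names")
  bad <- setdiff(unique(as.vector(G)), GENO_CODES)
  if (length(bad))
    stop("invalid genotype codes: ", paste(bad, collapse = ", "))
  invisible(G)
}

#' Numeric coding of genotype calls
#'
#' Codes calls as the dosage of the B allele: A = 0, B = 1 and, depending on
#' `het`, H = 0.5 (`"half"`) or NA (`"exclude"`). Missing calls are NA.
#'
#' @param G genotype matrix (A/B/H/N).
#' @param het how heterozygotes are coded.
#' @return numeric matrix with the same dimnames as `G`.
#' @export
geno_numeric <- function(G, het = c("half", "exclude")) {
  het <- match.arg(het)
  X <- matrix(NA_real_, nrow(G), ncol(G), dimnames = dimnames(G))
  X[G == "A"] <- 0
  X[G == "B"] <- 1
  if (het == "half") X[G == "H"] <- 0.5
  X
}

flip_calls <- function(x) {
  y <- x
  y[x == "A"] <- "B"
  y[x == "B"] <- "A"
  y
}

#' Write / read a genotype matrix as TSV
#'
#' Lines in rows (first column `line`), loci in columns, calls coded A/B/H/N.
#' Round-trips exactly.
#'
#' @param G genotype matrix.
#' @param path file path.
#' @return `read_genotype_matrix` returns the genotype matrix.
#' @export
write_genotype_matrix <- function(G, path) {
  validate_genotype_matrix(G)
  df <- data.frame(line = rownames(G), G, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genotype_matrix
#' @export
read_genotype_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          colClasses = "character")
  if (names(df)[1] != "line")
    stop("malformed genotype file (expected first column 'line'): ", path)
  G <- as.matrix(df[, -1, drop = FALSE])
  rownames(G) <- df$line
  validate_genotype_matrix(G)
  G
}

#' Write / read a genetic map as CSV
#'
#' Columns: locus, linkage_group, position_cM, status plus any placement
#' provenance columns (anchor1, rf1, anchor2, rf2, source_population).
#' Positions may be negative (distal placements). Round-trips exactly.
#'
#' @param map genetic map data frame.
#' @param path file path.
#' @return `read_map` returns the map data frame.
#' @export
write_map <- function(map, path) {
  stopifnot(all(c("locus", "linkage_group", "position_cM") %in% names(map)))
  utils::write.csv(map, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_map
#' @export
read_map <- function(path) {
  map <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("locus", "linkage_group", "position_cM")
  if (!all(need %in% names(map)))
    stop("malformed map file (need locus, linkage_group, position_cM): ", path)
  if (any(!is.finite(map$position_cM)))
    stop("non-finite map position in ", path)
  map
}

#' Write / read per-line tag read counts (long TSV: line, tag, count)
#'
#' @param counts line x tag integer matrix.
#' @param path file path.
#' @return `read_tag_counts` returns the counts matrix.
#' @export
write_tag_counts <- function(counts, path) {
  df <- data.frame(
    line  = rep(rownames(counts), times = ncol(counts)),
    tag   = rep(colnames(counts), each = nrow(counts)),
    count = as.vector(counts)
  )
  df <- df[order(df$line, df$tag), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tag_counts
#' @export
read_tag_counts <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  if (!all(c("line", "tag", "count") %in% names(df)))
    stop("malformed tag-count file: ", path)
  if (any(df$count < 0)) stop("negative tag count in ", path)
  lines <- sort(unique(df$line)); tags <- sort(unique(df$tag))
  m <- matrix(0L, length(lines), length(tags), dimnames = list(lines, tags))
  m[cbind(match(df$line, lines), match(df$tag, tags))] <- as.integer(df$count)
  m
}

#' Export genotype calls as VCF
#'
#' Write-only export. GBS tags carry no genome coordinates, so all records
#' are emitted on contig `UNPLACED` with positions equal to the catalog
#' index (1-based); REF/ALT are the two tag alleles when a SNP catalog is
#' supplied, otherwise symbolic A/B.
#'
#' @param G genotype matrix.
#' @param path output path.
#' @param snps optional SNP catalog (data frame with name, alleles) matching
#'   the loci of `G`.
#' @export
write_vcf <- function(G, path, snps = NULL) {
  validate_genotype_matrix(G)
  ref <- rep("A", ncol(G)); alt <- rep("B", ncol(G))
  if (!is.null(snps)) {
    idx <- match(colnames(G), snps$name)
    al <- strsplit(snps$alleles[idx], "/", fixed = TRUE)
    ok <- !is.na(idx)
    ref[ok] <- vapply(al[ok], `[`, "", 1)
    alt[ok] <- vapply(al[ok], `[`, "", 2)
  }
  gt <- matrix("./.", ncol(G), nrow(G))
  conv <- c(A = "0/0", B = "1/1", H = "0/1", N = "./.")
  gt[] <- conv[t(G)]
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##contig=<ID=UNPLACED>",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(G)), collapse = "\t")), con)
  body <- cbind("UNPLACED", seq_len(ncol(G)), colnames(G), ref, alt, ".", ".",
                ".", "GT", gt)
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' Read and validate a barcode key file
#'
#' CSV with columns flowcell, lane, barcode, sample. (flowcell, lane,
#' barcode) must be unique and barcodes within a lane prefix-free, so that
#' demultiplexing is unambiguous.
#'
#' @param path CSV path, or a data frame with the same columns.
#' @return validated key data frame.
#' @export
read_key_file <- function(path) {
  key <- if (is.data.frame(path)) path else
    utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("flowcell", "lane", "barcode", "sample")
  if (!all(need %in% names(key)))
    stop("key file must have columns: ", paste(need, collapse = ", "))
  if (!all(grepl("^[ACGT]{4,10}$", key$barcode)))
    stop("barcodes must be 4-10 bp of ACGT")
  id <- paste(key$flowcell, key$lane, key$barcode)
  if (anyDuplicated(id))
    stop("duplicate (flowcell, lane, barcode) entries in key file")
  for (ln in split(key$barcode, paste(key$flowcell, key$lane))) {
    for (i in seq_along(ln)) for (j in seq_along(ln)) {
      if (i != j && startsWith(ln[i], ln[j]))
        stop("barcode set not prefix-free within a lane: ",
             ln[j], " prefixes ", ln[i])
    }
  }
  key
}

#' Demultiplex barcoded GBS reads
#'
#' A read is assigned to a sample iff it begins with that sample's exact
#' barcode immediately followed by the restriction cut-site remnant, and
#' contains no unreadable base (N). This is a desk-scale reference
#' implementation, not a performance tool. The good-barcoded-read counts per
#' sample feed [depth_index()].
#'
#' @param reads FASTQ path or a character vector of read sequences.
#' @param key key file (path or data frame, see [read_key_file()]).
#' @param cutsite_remnant remnant left by the barcode-side enzyme; PstI
#'   (CTGCAG) leaves `"TGCAG"`.
#' @return list with `assignments` (per-sample character vectors of read
#'   sequences) and `stats` (n_reads, n_good, good_fraction, per-sample
#'   counts).
#' @export
demultiplex <- function(reads, key, cutsite_remnant = "TGCAG") {
  key <- read_key_file(key)
  if (is.character(reads) && length(reads) == 1 && file.exists(reads))
    reads <- as.character(Biostrings::readDNAStringSet(reads, format = "fastq"))
  has_n <- grepl("N", reads, fixed = TRUE)
  sample_of <- rep(NA_character_, length(reads))
  for (i in seq_len(nrow(key))) {
    pat <- paste0(key$barcode[i], cutsite_remnant)
    hit <- !has_n & is.na(sample_of) & startsWith(reads, pat)
    sample_of[hit] <- key$sample[i]
  }
  good <- !is.na(sample_of)
  assignments <- split(reads[good], sample_of[good])
  counts <- vapply(key$sample, function(s) sum(sample_of == s, na.rm = TRUE), 0L)
  list(assignments = assignments,
       stats = list(n_reads = length(reads), n_good = sum(good),
                    good_fraction = if (length(reads)) sum(good) / length(reads) else NA_real_,
                    per_sample = counts))
}
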