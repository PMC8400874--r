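# Genotype panel I/O: PLINK PED/MAP, binary BED/BIM/FAM (SNP-major) and a plain
# TSV dialect, plus the call-rate QC filter, allele frequencies and the
# physical -> genetic position mapping.

PLINK_BED_MAGIC <- as.raw(c(0x6c, 0x1b, 0x01))

#' Construct a genotype panel
#'
#' A `genotype_panel` bundles a dosage matrix (samples x markers, entries in
#' \{0, 1, 2, NA\} counting the coded allele), a marker map and a sample table.
#' Markers are stored sorted by (chromosome, bp); the genotype columns are
#' permuted accordingly.
#'
#' @param G integer matrix, samples x markers, entries 0/1/2/NA.
#' @param markers data.frame with columns `chrom`, `marker_id`, `cm`
#'   (centiMorgans, 0 when unknown), `bp` (1-based physical position),
#'   `coded_allele`, `other_allele`, and optionally `gpos` (Morgans).
#' @param samples data.frame with columns `sample_id` and `group`.
#' @return An object of class `genotype_panel`.
#' @export
genotype_panel <- function(G, markers, samples) {
  stopifnot(is.matrix(G))
  if (nrow(G) != nrow(samples))
    stop("genotype matrix has ", nrow(G), " rows but ", nrow(samples), " samples")
  if (ncol(G) != nrow(markers))
    stop("genotype matrix has ", ncol(G), " columns but ", nrow(markers), " markers")
  bad <- !(G %in% c(0L, 1L, 2L)) & !is.na(G)
  if (any(bad)) stop("genotypes must be 0, 1, 2 or missing")
  if (anyDuplicated(markers$marker_id))
    stop("duplicate marker id: ",
         markers$marker_id[anyDuplicated(markers$marker_id)])
  if (anyDuplicated(samples$sample_id)) stop("duplicate sample id")
  if (is.null(markers$gpos)) markers$gpos <- NA_real_

  # sort markers by (chrom, bp), numerically on chromosome when possible
  num <- suppressWarnings(as.numeric(markers$chrom))
  ord <- if (anyNA(num)) order(markers$chrom, markers$bp) else order(num, markers$bp)
  markers <- markers[ord, , drop = FALSE]
  G <- G[, ord, drop = FALSE]
  rownames(markers) <- NULL

  dup <- unlist(tapply(markers$bp, markers$chrom, function(b) duplicated(b)))
  if (any(dup)) stop("duplicated bp position within a chromosome")

  storage.mode(G) <- "integer"
  dimnames(G) <- list(samples$sample_id, markers$marker_id)
  structure(list(G = G, markers = markers, samples = samples),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat("genotype_panel:", nrow(x$G), "samples x", ncol(x$G), "markers on",
      length(unique(x$markers$chrom)), "chromosome(s)\n")
  miss <- mean(is.na(x$G))
  cat(sprintf("  missingness %.2f%%; groups: %s\n", 100 * miss,
              paste(unique(x$samples$group), collapse = ", ")))
  invisible(x)
}

read_map_file <- function(path) {
  if (!file.exists(path)) stop("map file not found: ", path)
  tab <- tryCatch(
    read.table(path, header = FALSE, stringsAsFactors = FALSE,
               colClasses = "character"),
    error = function(e) stop("malformed map file ", path, ": ", conditionMessage(e)))
  if (ncol(tab) == 3L) tab <- cbind(tab[, 1:2], "0", tab[, 3])
  if (ncol(tab) < 4L) stop("map file ", path, " must have 3 or 4 columns")
  data.frame(chrom = tab[[1]], marker_id = tab[[2]],
             cm = as.numeric(tab[[3]]), bp = as.numeric(tab[[4]]),
             coded_allele = NA_character_, other_allele = NA_character_,
             gpos = NA_real_, stringsAsFactors = FALSE)
}

parse_ped_genotypes <- function(allele_mat) {
  # allele_mat: samples x (2*markers) character; returns list(G, coded, other)
  m <- ncol(allele_mat) / 2L
  n <- nrow(allele_mat)
  G <- matrix(NA_integer_, n, m)
  coded <- other <- character(m)
  for (j in seq_len(m)) {
    a1 <- allele_mat[, 2L * j - 1L]
    a2 <- allele_mat[, 2L * j]
    ok <- a1 != "0" & a2 != "0"
    seen <- c(rbind(a1[ok], a2[ok]))          # file order
    uniq <- unique(seen)
    if (length(uniq) > 2L)
      stop("marker column ", j, " has more than two alleles: ",
           paste(uniq, collapse = ", "))
    cj <- if (length(uniq) >= 1L) uniq[1L] else "A"
    oj <- if (length(uniq) == 2L) uniq[2L] else if (cj == "B") "A" else "B"
    G[ok, j] <- (a1[ok] == cj) + (a2[ok] == cj)
    coded[j] <- cj; other[j] <- oj
  }
  list(G = G, coded = coded, other = other)
}

read_ped <- function(prefix) {
  markers <- read_map_file(paste0(prefix, ".map"))
  ped_path <- paste0(prefix, ".ped")
  if (!file.exists(ped_path)) stop("ped file not found: ", ped_path)
  lines <- readLines(ped_path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(trimws(lines), "[ \t]+")
  want <- 6L + 2L * nrow(markers)
  nf <- lengths(fields)
  if (any(nf != want))
    stop("malformed PED file ", ped_path, ": line ",
         which(nf != want)[1], " has ", nf[nf != want][1],
         " fields, expected ", want)
  mat <- do.call(rbind, fields)
  samples <- data.frame(sample_id = mat[, 2], group = mat[, 1],
                        stringsAsFactors = FALSE)
  parsed <- parse_ped_genotypes(mat[, -(1:6), drop = FALSE])
  markers$coded_allele <- parsed$coded
  markers$other_allele <- parsed$other
  genotype_panel(parsed$G, markers, samples)
}

read_fam <- function(path) {
  if (!file.exists(path)) stop("fam file not found: ", path)
  tab <- read.table(path, header = FALSE, stringsAsFactors = FALSE,
                    colClasses = "character")
  if (ncol(tab) < 2L) stop("malformed FAM file ", path)
  data.frame(sample_id = tab[[2]], group = tab[[1]], stringsAsFactors = FALSE)
}

read_bim <- function(path) {
  if (!file.exists(path)) stop("bim file not found: ", path)
  tab <- read.table(path, header = FALSE, stringsAsFactors = FALSE,
                    colClasses = "character")
  if (ncol(tab) != 6L) stop("malformed BIM file ", path, ": expected 6 columns")
  data.frame(chrom = tab[[1]], marker_id = tab[[2]], cm = as.numeric(tab[[3]]),
             bp = as.numeric(tab[[4]]), coded_allele = tab[[5]],
             other_allele = tab[[6]], gpos = NA_real_, stringsAsFactors = FALSE)
}

# 2-bit PLINK codes -> coded-allele dosage: 00 hom-A1 = 2, 01 missing,
# 10 het = 1, 11 hom-A2 = 0
bed_code_to_dosage <- c(2L, NA_integer_, 1L, 0L)

read_bed <- function(prefix) {
  markers <- read_bim(paste0(prefix, ".bim"))
  samples <- read_fam(paste0(prefix, ".fam"))
  bed_path <- paste0(prefix, ".bed")
  if (!file.exists(bed_path)) stop("bed file not found: ", bed_path)
  raw <- readBin(bed_path, "raw", n = file.size(bed_path))
  if (length(raw) < 3L || !identical(raw[1:3], PLINK_BED_MAGIC))
    stop("not a SNP-major PLINK BED file (bad magic bytes): ", bed_path)
  n <- nrow(samples); m <- nrow(markers)
  bpm <- ceiling(n / 4)
  body <- raw[-(1:3)]
  if (length(body) != bpm * m)
    stop("BED file ", bed_path, " has ", length(body),
         " data bytes; expected ", bpm * m)
  bytes <- matrix(as.integer(body), nrow = bpm, ncol = m)
  G <- matrix(NA_integer_, n, m)
  for (k in 1:4) {
    if (k > n) break
    idx <- seq.int(k, n, by = 4L)          # samples carried in bit-pair k
    rows <- ((idx - 1L) %/% 4L) + 1L
    codes <- bitwAnd(bitwShiftR(bytes[rows, , drop = FALSE],
                                2L * (k - 1L)), 3L)
    G[idx, ] <- bed_code_to_dosage[codes + 1L]
  }
  genotype_panel(G, markers, samples)
}

read_tsv_panel <- function(prefix) {
  markers <- read_map_file(paste0(prefix, ".map"))
  tsv_path <- paste0(prefix, ".tsv")
  if (!file.exists(tsv_path)) stop("tsv file not found: ", tsv_path)
  tab <- read.table(tsv_path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
  if (colnames(tab)[1] != "sample_id")
    stop("malformed TSV panel ", tsv_path, ": first column must be sample_id")
  ids <- colnames(tab)[-1]
  if (!setequal(ids, markers$marker_id) || length(ids) != nrow(markers))
    stop("TSV header marker ids do not match the map file")
  G <- as.matrix(tab[, markers$marker_id, drop = FALSE])
  markers$coded_allele <- "A"; markers$other_allele <- "B"
  genotype_panel(G, markers,
                 data.frame(sample_id = as.character(tab$sample_id),
                            group = NA_character_, stringsAsFactors = FALSE))
}

#' Read a genotype panel
#'
#' Reads a diploid SNP panel from PLINK text (`.ped` + `.map`), PLINK binary
#' (`.bed` + `.bim` + `.fam`, SNP-major) or a TSV dosage matrix
#' (`.tsv` + `.map`). Markers are returned sorted by (chromosome, bp) with the
#' genotype columns permuted consistently; missing genotypes are preserved.
#'
#' @param prefix file path prefix (without extension).
#' @param dialect one of `"ped"`, `"bed"`, `"tsv"`.
#' @return A [genotype_panel()].
#' @export
read_panel <- function(prefix, dialect = c("ped", "bed", "tsv")) {
  dialect <- match.arg(dialect)
  switch(dialect, ped = read_ped(prefix), bed = read_bed(prefix),
         tsv = read_tsv_panel(prefix))
}

write_map_file <- function(markers, path) {
  write.table(data.frame(markers$chrom, markers$marker_id,
                         format(markers$cm, trim = TRUE, scientific = FALSE),
                         format(markers$bp, trim = TRUE, scientific = FALSE)),
              path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
}

#' Write a genotype panel
#'
#' Inverse of [read_panel()]; a read/write/read round trip reproduces the
#' genotype matrix, marker map and sample table exactly.
#'
#' @param panel a [genotype_panel()].
#' @param prefix output file path prefix.
#' @param dialect one of `"ped"`, `"bed"`, `"tsv"`.
#' @return `prefix`, invisibly.
#' @export
write_panel <- function(panel, prefix, dialect = c("ped", "bed", "tsv")) {
  dialect <- match.arg(dialect)
  mk <- panel$markers; G <- panel$G
  grp <- ifelse(is.na(panel$samples$group), "0", panel$samples$group)
  if (dialect == "ped") {
    write_map_file(mk, paste0(prefix, ".map"))
    n <- nrow(G); m <- ncol(G)
    al <- matrix("0", n, 2L * m)
    for (j in seq_len(m)) {
      g <- G[, j]
      a1 <- ifelse(is.na(g), "0", ifelse(g >= 1, mk$coded_allele[j], mk$other_allele[j]))
      a2 <- ifelse(is.na(g), "0", ifelse(g == 2, mk$coded_allele[j], mk$other_allele[j]))
      al[, 2L * j - 1L] <- a1; al[, 2L * j] <- a2
    }
    lines <- paste(grp, panel$samples$sample_id, "0", "0", "0", "-9",
                   apply(al, 1, paste, collapse = " "))
    writeLines(lines, paste0(prefix, ".ped"))
  } else if (dialect == "bed") {
    write.table(data.frame(mk$chrom, mk$marker_id,
                           format(mk$cm, trim = TRUE, scientific = FALSE),
                           format(mk$bp, trim = TRUE, scientific = FALSE),
                           mk$coded_allele, mk$other_allele),
                paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    write.table(data.frame(grp, panel$samples$sample_id, "0", "0", "0", "-9"),
                paste0(prefix, ".fam"), sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    n <- nrow(G); m <- ncol(G); bpm <- ceiling(n / 4)
    # dosage -> 2-bit code
    code <- matrix(1L, n, m)                       # 01 = missing
    code[!is.na(G) & G == 2L] <- 0L
    code[!is.na(G) & G == 1L] <- 2L
    code[!is.na(G) & G == 0L] <- 3L
    bytes <- matrix(0L, bpm, m)
    for (k in 1:4) {
      if (k > n) break
      idx <- seq.int(k, n, by = 4L)
      rows <- ((idx - 1L) %/% 4L) + 1L
      add <- matrix(0L, bpm, m)
      add[rows, ] <- bitwShiftL(code[idx, , drop = FALSE], 2L * (k - 1L))
      bytes <- bytes + add
    }
    con <- file(paste0(prefix, ".bed"), "wb")
    on.exit(close(con))
    writeBin(PLINK_BED_MAGIC, con)
    writeBin(as.raw(as.vector(bytes)), con)
  } else {
    write_map_file(mk, paste0(prefix, ".map"))
    tab <- data.frame(sample_id = panel$samples$sample_id, G,
                      check.names = FALSE, stringsAsFactors = FALSE)
    write.table(tab, paste0(prefix, ".tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(prefix)
}

#' Read a two-column sample-to-group label file
#'
#' @param path TSV with columns sample_id, group (no header required).
#' @return data.frame with columns `sample_id`, `group`.
#' @export
read_groups <- function(path) {
  if (!file.exists(path)) stop("group file not found: ", path)
  tab <- read.table(path, header = FALSE, sep = "\t", stringsAsFactors = FALSE,
                    colClasses = "character")
  if (identical(tolower(tab[1, 1]), "sample_id")) tab <- tab[-1, , drop = FALSE]
  if (ncol(tab) < 2L) stop("group file must have two columns: sample_id, group")
  data.frame(sample_id = tab[[1]], group = tab[[2]], stringsAsFactors = FALSE)
}

#' Attach group labels to a panel
#'
#' @param panel a [genotype_panel()].
#' @param groups data.frame as returned by [read_groups()].
#' @return The panel with its `samples$group` column replaced.
#' @export
set_groups <- function(panel, groups) {
  idx <- match(panel$samples$sample_id, groups$sample_id)
  if (anyNA(idx))
    stop("no group label for sample(s): ",
         paste(panel$samples$sample_id[is.na(idx)], collapse = ", "))
  panel$samples$group <- groups$group[idx]
  rownames(panel$G) <- panel$samples$sample_id
  panel
}

#' Remove markers with low call rate
#'
#' The only genotype QC applied: markers whose fraction of non-missing calls
#' falls below `min_call_rate` are dropped (default 95%). Samples are never
#' filtered.
#'
#' @param panel a [genotype_panel()].
#' @param min_call_rate minimum fraction of non-missing genotypes, in (0, 1].
#' @return The filtered panel, with attribute `n_removed` giving the number of
#'   markers dropped.
#' @export
filter_call_rate <- function(panel, min_call_rate = 0.95) {
  if (!is.numeric(min_call_rate) || min_call_rate <= 0 || min_call_rate > 1)
    stop("min_call_rate must be in (0, 1]")
  rate <- colMeans(!is.na(panel$G))
  keep <- rate >= min_call_rate
  if (!any(keep))
    stop("call-rate filter removed every marker; review the threshold (",
         min_call_rate, ")")
  out <- panel
  out$G <- panel$G[, keep, drop = FALSE]
  out$markers <- panel$markers[keep, , drop = FALSE]
  rownames(out$markers) <- NULL
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Coded-allele frequencies
#'
#' Per-marker frequency of the coded allele, computed from non-missing calls
#' only: p = (dosage sum) / (2 * n_obs). Frequencies are a model input: the
#' emission probabilities of every HMM state depend on them.
#'
#' @param panel a [genotype_panel()].
#' @param by_group if `TRUE`, return a named list of per-group frequency
#'   tables (emissions for breed-stratified data are better calibrated within
#'   group).
#' @return data.frame with columns `marker_id`, `p`, `n_obs`, or a named list
#'   of such data.frames when `by_group = TRUE`.
#' @export
allele_frequencies <- function(panel, by_group = FALSE) {
  freq1 <- function(G) {
    n_obs <- colSums(!is.na(G))
    if (any(n_obs == 0L))
      stop("marker(s) with zero non-missing calls: ",
           paste(head(colnames(G)[n_obs == 0L]), collapse = ", "),
           " (apply filter_call_rate first)")
    data.frame(marker_id = colnames(G),
               p = colSums(G, na.rm = TRUE) / (2 * n_obs),
               n_obs = n_obs, row.names = NULL, stringsAsFactors = FALSE)
  }
  if (!by_group) return(freq1(panel$G))
  grps <- unique(panel$samples$group)
  setNames(lapply(grps, function(g)
    freq1(panel$G[panel$samples$group %in% g, , drop = FALSE])), grps)
}

#' Place markers on the genetic (Morgan) scale
#'
#' When the marker map carries an explicit centiMorgan column (any non-zero
#' entry) it takes precedence: gpos = cM / 100. Otherwise physical positions
#' are converted at a constant rate: gpos = bp * cm_per_mb / 1e8 Morgans
#' (default 1 cM/Mb, the standard fallback for livestock SNP arrays).
#'
#' @param x a [genotype_panel()] or a marker-map data.frame.
#' @param cm_per_mb recombination rate in cM per Mb; must be non-negative.
#' @return The input with its `gpos` column (Morgans) filled in.
#' @export
assign_gpos <- function(x, cm_per_mb = 1.0) {
  if (!is.numeric(cm_per_mb) || cm_per_mb < 0)
    stop("cm_per_mb must be non-negative")
  map <- if (inherits(x, "genotype_panel")) x$markers else x
  has_cm <- !is.null(map$cm) && any(!is.na(map$cm) & map$cm > 0)
  map$gpos <- if (has_cm) map$cm / 100 else map$bp * cm_per_mb / 1e8
  bad <- unlist(tapply(map$gpos, map$chrom, function(g) diff(g) < 0))
  if (length(bad) && any(bad, na.rm = TRUE))
    stop("genetic positions must be non-decreasing within a chromosome")
  if (inherits(x, "genotype_panel")) { x$markers <- map; x } else map
}
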