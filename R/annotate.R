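# Overlap of decoded HBD segments with user-supplied genomic feature intervals
# (QTL, genes). Coordinates: segments are 1-based inclusive (marker positions);
# feature files are BED, 0-based half-open. Intersection is delegated to
# IRanges/GenomicRanges interval trees.

#' Read a feature interval file (BED 3+2)
#'
#' Expects tab-separated columns chrom, start, end (0-based half-open) and
#' optionally name and category (free-form, e.g. "Meat and Carcass").
#'
#' @param path BED file path.
#' @return data.frame of class `feature_set` with columns `chrom`, `start`,
#'   `end` (0-based half-open), `name`, `category`.
#' @export
read_features <- function(path) {
  if (!file.exists(path)) stop("feature file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop("malformed BED line ", which(nf < 3L)[1], ": fewer than 3 columns")
  starts <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L)))
  ends <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3L)))
  bad <- which(is.na(starts) | is.na(ends))
  if (length(bad))
    stop("malformed BED line ", bad[1], ": non-numeric coordinates")
  bad <- which(ends <= starts)
  if (length(bad))
    stop("malformed BED line ", bad[1], ": end must exceed start")
  out <- data.frame(
    chrom = vapply(fields, `[`, "", 1L),
    start = starts, end = ends,
    name = ifelse(nf >= 4L, vapply(fields, function(f) f[4], ""),
                  paste0("feature_", seq_along(fields))),
    category = ifelse(nf >= 5L, vapply(fields, function(f) f[5], ""), "unknown"),
    stringsAsFactors = FALSE)
  class(out) <- c("feature_set", "data.frame")
  out
}

#' Overlap HBD segments with feature intervals
#'
#' Segments (1-based inclusive) are converted to 0-based half-open by
#' (start_bp - 1, end_bp); a feature overlaps a segment when the ranges
#' intersect by at least one base. A feature overlapping several segments is
#' listed once per segment in `per_segment`, but counted once in the
#' per-category and per-chromosome totals of distinct features overlapped.
#'
#' @param segments segment data.frame (see [path_to_segments()]).
#' @param features a `feature_set` from [read_features()], or a data.frame
#'   with the same columns.
#' @return List with `per_segment` (one row per segment-feature pair),
#'   `by_category` (`category`, `n_features` distinct features overlapped,
#'   `n_hits` segment-feature pairs) and `by_chrom` (distinct features
#'   overlapped per chromosome).
#' @export
overlap_segments <- function(segments, features) {
  if (nrow(segments) == 0 || nrow(features) == 0) {
    empty <- data.frame()
    return(list(per_segment = data.frame(),
                by_category = data.frame(category = character(0),
                                         n_features = integer(0),
                                         n_hits = integer(0)),
                by_chrom = data.frame(chrom = character(0),
                                      n_features = integer(0))))
  }
  seg_gr <- GenomicRanges::GRanges(
    seqnames = as.character(segments$chrom),
    ranges = IRanges::IRanges(start = segments$start_bp, end = segments$end_bp))
  feat_gr <- GenomicRanges::GRanges(
    seqnames = as.character(features$chrom),
    ranges = IRanges::IRanges(start = features$start + 1, end = features$end))
  hits <- GenomicRanges::findOverlaps(seg_gr, feat_gr)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  per_segment <- data.frame(
    sample_id = segments$sample_id[qi], group = segments$group[qi],
    chrom = segments$chrom[qi], class_rate = segments$class_rate[qi],
    start_bp = segments$start_bp[qi], end_bp = segments$end_bp[qi],
    feature = features$name[si], category = features$category[si],
    stringsAsFactors = FALSE)
  uniq <- !duplicated(si)
  fu <- data.frame(chrom = features$chrom[si[uniq]],
                   category = features$category[si[uniq]],
                   stringsAsFactors = FALSE)
  by_category <- merge(
    aggregate(list(n_features = fu$category), by = list(category = fu$category),
              FUN = length),
    aggregate(list(n_hits = per_segment$category),
              by = list(category = per_segment$category), FUN = length),
    by = "category")
  by_chrom <- aggregate(list(n_features = fu$chrom),
                        by = list(chrom = fu$chrom), FUN = length)
  list(per_segment = per_segment,
       by_category = by_category[order(by_category$category), , drop = FALSE],
       by_chrom = by_chrom[order(by_chrom$chrom), , drop = FALSE])
}
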