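# From Viterbi state paths to HBD segment records and the per-group summary
# surfaces: per-class counts and mean lengths, per-animal averages, and the
# five-number summary of the inbreeding coefficient.

#' Convert a Viterbi state path into HBD segments
#'
#' Maximal runs of a constant HBD state become one segment each; non-HBD runs
#' emit nothing; runs never span chromosome boundaries, and adjacent runs of
#' different HBD classes are distinct segments. Segment bounds are the
#' physical positions of the first and last marker of the run (no extension
#' toward flanking markers), matching SNP-count based length reporting.
#'
#' @param path integer state per marker (HBD classes 1..S-1, non-HBD = S), as
#'   returned by [viterbi()].
#' @param map marker map (`chrom`, `bp`, `gpos`, `marker_id`).
#' @param sample_id,group labels copied into every record.
#' @param model the [hbd_model()] that produced the path; supplies the class
#'   rates.
#' @return data.frame with columns `sample_id`, `group`, `chrom`,
#'   `class_rate`, `start_bp`, `end_bp`, `n_snps`, `length_mb`,
#'   `length_morgans` (zero rows when the path is entirely non-HBD).
#' @export
path_to_segments <- function(path, map, sample_id, group, model = default_model()) {
  if (length(path) != nrow(map))
    stop("path length (", length(path), ") does not match marker count (",
         nrow(map), ")")
  S <- model$n_states
  # run boundaries: state change or chromosome change
  chrom <- as.character(map$chrom)
  new_run <- c(TRUE, path[-1] != path[-length(path)] |
                     chrom[-1] != chrom[-length(chrom)])
  run_id <- cumsum(new_run)
  starts <- which(new_run)
  ends <- c(starts[-1] - 1L, length(path))
  state <- path[starts]
  keep <- state < S
  starts <- starts[keep]; ends <- ends[keep]; state <- state[keep]
  data.frame(sample_id = rep(sample_id, length(starts)),
             group = rep(group, length(starts)),
             chrom = chrom[starts],
             class_rate = model$rates[state],
             start_bp = map$bp[starts],
             end_bp = map$bp[ends],
             n_snps = ends - starts + 1L,
             length_mb = (map$bp[ends] - map$bp[starts]) / 1e6,
             length_morgans = map$gpos[ends] - map$gpos[starts],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Decode HBD segments for every individual of a fitted panel
#'
#' Runs [viterbi()] under each individual's fitted model and converts the
#' paths to segment records.
#'
#' @param panel a [genotype_panel()].
#' @param fit an `hbd_panel_fit` from [fit_hbd()].
#' @return data.frame of segments (see [path_to_segments()]).
#' @export
decode_segments <- function(panel, fit) {
  segs <- lapply(seq_len(nrow(panel$samples)), function(i) {
    f <- fit$fits[[i]]
    fr <- if (is.data.frame(fit$freqs)) fit$freqs else
      fit$freqs[[panel$samples$group[i]]]
    v <- viterbi(panel$G[i, ], fr, panel$markers, f$model)
    path_to_segments(v$path, panel$markers, panel$samples$sample_id[i],
                     panel$samples$group[i], f$model)
  })
  do.call(rbind, segs)
}

#' Per-group, per-class segment summary
#'
#' Reproduces the layout of a "number and length (Mb) of HBD segments" table:
#' per group x class, segment count and mean length with its standard error
#' (sample SD / sqrt(count)); per group, total segments, mean segments per
#' animal (denominator includes animals with zero segments), mean length and
#' mean SNP count.
#'
#' @param segments segment data.frame from [path_to_segments()] /
#'   [decode_segments()]; may have zero rows.
#' @param samples data.frame with `sample_id` and `group` for every analysed
#'   animal (defines the per-animal denominators).
#' @return List of class `segment_summary` with data.frames `by_class`
#'   (`group`, `class_rate`, `n`, `mean_length_mb`, `se_length_mb`) and
#'   `by_group` (`group`, `n_animals`, `n_segments`, `segments_per_animal`,
#'   `mean_length_mb`, `mean_n_snps`).
#' @export
summarize_segments <- function(segments, samples) {
  if (nrow(samples) < 1L) stop("need at least one sample")
  if (nrow(segments) > 0) {
    unknown <- setdiff(unique(segments$group), unique(samples$group))
    if (length(unknown))
      stop("segment group label(s) not present in sample table: ",
           paste(unknown, collapse = ", "))
  }
  groups <- unique(samples$group)
  by_class <- do.call(rbind, lapply(groups, function(g) {
    sg <- segments[segments$group == g, , drop = FALSE]
    if (nrow(sg) == 0)
      return(data.frame(group = character(0), class_rate = numeric(0),
                        n = integer(0), mean_length_mb = numeric(0),
                        se_length_mb = numeric(0)))
    rates <- sort(unique(sg$class_rate))
    do.call(rbind, lapply(rates, function(r) {
      len <- sg$length_mb[sg$class_rate == r]
      data.frame(group = g, class_rate = r, n = length(len),
                 mean_length_mb = mean(len),
                 se_length_mb = if (length(len) > 1)
                   sd(len) / sqrt(length(len)) else NA_real_)
    }))
  }))
  by_group <- do.call(rbind, lapply(groups, function(g) {
    sg <- segments[segments$group == g, , drop = FALSE]
    n_animals <- sum(samples$group == g)
    data.frame(group = g, n_animals = n_animals, n_segments = nrow(sg),
               segments_per_animal = nrow(sg) / n_animals,
               mean_length_mb = if (nrow(sg)) mean(sg$length_mb) else NaN,
               mean_n_snps = if (nrow(sg)) mean(sg$n_snps) else NaN)
  }))
  rownames(by_class) <- rownames(by_group) <- NULL
  structure(list(by_class = by_class, by_group = by_group),
            class = "segment_summary")
}

#' @export
print.segment_summary <- function(x, ...) {
  cat("Segments per group:\n"); print(x$by_group)
  cat("\nPer class:\n"); print(x$by_class)
  invisible(x)
}

#' Longest segments of selected classes
#'
#' Filters segments to the given classes (e.g. the two most recent, rates 2
#' and 4), ranks them by length, and tallies the filtered segments per
#' chromosome and group — the shape of a "longest recent segments by
#' chromosome" figure.
#'
#' @param segments segment data.frame.
#' @param classes numeric vector of class rates to keep.
#' @param top_n how many top-ranked segments to return.
#' @return List with `top` (segments sorted by `length_mb` descending, ties by
#'   chromosome then start position, truncated to `top_n`) and `by_chrom`
#'   (data.frame `chrom`, `group`, `n` over all filtered segments).
#' @export
longest_segments <- function(segments, classes, top_n = 10L) {
  if (length(classes) == 0) stop("classes must be non-empty")
  sel <- segments[segments$class_rate %in% classes, , drop = FALSE]
  num <- suppressWarnings(as.numeric(sel$chrom))
  ckey <- if (anyNA(num)) rank(sel$chrom) else num
  ord <- order(-sel$length_mb, ckey, sel$start_bp)
  top <- sel[ord, , drop = FALSE][seq_len(min(top_n, nrow(sel))), , drop = FALSE]
  rownames(top) <- NULL
  by_chrom <- if (nrow(sel)) {
    agg <- aggregate(list(n = sel$start_bp),
                     by = list(chrom = sel$chrom, group = sel$group), FUN = length)
    agg[order(agg$chrom, agg$group), , drop = FALSE]
  } else data.frame(chrom = character(0), group = character(0), n = integer(0))
  rownames(by_chrom) <- NULL
  list(top = top, by_chrom = by_chrom)
}

#' Per-group summary statistics of the inbreeding coefficient
#'
#' Min, first quartile, median, mean, third quartile and max of F per group,
#' with quartiles by linear interpolation (quantile type 7).
#'
#' @param F numeric vector of per-individual inbreeding coefficients.
#' @param groups group label per individual.
#' @return data.frame with one row per group and columns `group`, `n`, `min`,
#'   `q1`, `median`, `mean`, `q3`, `max`.
#' @export
inbreeding_table <- function(F, groups) {
  if (length(F) != length(groups)) stop("F and groups must have equal length")
  if (length(F) == 0) stop("empty group: need at least one sample per group")
  out <- do.call(rbind, lapply(unique(groups), function(g) {
    x <- F[groups == g]
    if (length(x) == 0) stop("empty group: ", g)
    q <- quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    data.frame(group = g, n = length(x), min = min(x), q1 = q[1],
               median = q[2], mean = mean(x), q3 = q[3], max = max(x))
  }))
  rownames(out) <- NULL
  out
}

#' Export segments as BED intervals
#'
#' Writes segments in BED format (0-based half-open: start_bp - 1, end_bp)
#' with name `sample_id:R_<class>` for genome-browser use.
#'
#' @param segments segment data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_segments_bed <- function(segments, path) {
  bed <- data.frame(segments$chrom,
                    format(segments$start_bp - 1, trim = TRUE, scientific = FALSE),
                    format(segments$end_bp, trim = TRUE, scientific = FALSE),
                    paste0(segments$sample_id, ":R_", segments$class_rate))
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
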