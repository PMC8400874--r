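# File-level pipeline commands tying the modules together: simulate, fit,
# segments, summarize, overlap. Each command is a pure function of its
# configuration (plus the files it reads), so re-running with the same config
# and seed reproduces byte-identical outputs. A thin command-line wrapper
# lives in inst/cli/hbdscan.R.

#' Pipeline run configuration
#'
#' @param input_prefix path prefix of the genotype panel (for `run_fit` and
#'   downstream commands) or of the simulated output (for `run_simulate`).
#' @param dialect panel dialect: `"ped"`, `"bed"` or `"tsv"`.
#' @param out_dir output directory (created if needed).
#' @param min_call_rate marker QC threshold in (0, 1].
#' @param n_classes,eps model settings (see [default_model()]).
#' @param cm_per_mb physical-to-genetic conversion (see [assign_gpos()]).
#' @param groups_file optional two-column sample-to-group TSV.
#' @param features_bed optional BED file of intervals for `run_overlap`.
#' @param seed root seed for every stochastic step.
#' @param sim optional list overriding [sim_config()] fields for
#'   `run_simulate` (`n_chrom`, `markers_per_chrom`, `spacing_morgans`,
#'   `n_individuals`, `hbd_occupancy`: total genome fraction planted in HBD
#'   classes).
#' @param verbose print progress messages.
#' @return List of class `run_config`.
#' @export
run_config <- function(input_prefix, dialect = "ped", out_dir = ".",
                       min_call_rate = 0.95, n_classes = 10, eps = 0.001,
                       cm_per_mb = 1.0, groups_file = NULL,
                       features_bed = NULL, seed = 1, sim = list(),
                       verbose = FALSE) {
  if (!is.numeric(min_call_rate) || min_call_rate <= 0 || min_call_rate > 1)
    stop("config error: min_call_rate must be in (0, 1]")
  if (!dialect %in% c("ped", "bed", "tsv"))
    stop("config error: unknown dialect '", dialect, "'")
  if (!is.numeric(seed)) stop("config error: seed must be numeric")
  structure(list(input_prefix = input_prefix, dialect = dialect,
                 out_dir = out_dir, min_call_rate = min_call_rate,
                 n_classes = n_classes, eps = eps, cm_per_mb = cm_per_mb,
                 groups_file = groups_file, features_bed = features_bed,
                 seed = as.integer(seed), sim = sim, verbose = verbose),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror the [run_config()] arguments.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  do.call(run_config, yaml::read_yaml(path))
}

say <- function(cfg, ...) if (isTRUE(cfg$verbose)) message(...)

out_path <- function(cfg, name) {
  if (!dir.exists(cfg$out_dir)) dir.create(cfg$out_dir, recursive = TRUE)
  file.path(cfg$out_dir, name)
}

write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

load_panel <- function(cfg) {
  panel <- read_panel(cfg$input_prefix, cfg$dialect)
  if (!is.null(cfg$groups_file))
    panel <- set_groups(panel, read_groups(cfg$groups_file))
  panel <- filter_call_rate(panel, cfg$min_call_rate)
  say(cfg, "call-rate filter removed ", attr(panel, "n_removed"), " marker(s)")
  assign_gpos(panel, cfg$cm_per_mb)
}

#' Simulate a panel to disk
#'
#' Writes a simulated genotype panel (plus truth TSVs) under
#' `cfg$input_prefix`, using the model implied by the config (`n_classes`,
#' `eps`) with mixing derived from `cfg$sim$hbd_occupancy` (default 0.25 of
#' the genome in HBD classes, split equally among them).
#'
#' @param cfg a [run_config()].
#' @return The simulation list from [simulate_panel()], invisibly.
#' @export
run_simulate <- function(cfg) {
  sim_args <- cfg$sim
  model <- default_model(cfg$n_classes, cfg$eps)
  occ_hbd <- if (is.null(sim_args$hbd_occupancy)) 0.25 else sim_args$hbd_occupancy
  S <- model$n_states
  occ <- c(rep(occ_hbd / (S - 1), S - 1), 1 - occ_hbd)
  model <- hbd_model(model$rates, mixing_for_occupancy(occ, model$rates),
                     model$eps)
  cfg_fields <- sim_args[intersect(names(sim_args),
                                   c("n_chrom", "markers_per_chrom",
                                     "spacing_morgans", "n_individuals"))]
  sc <- do.call(sim_config, c(cfg_fields, list(model = model, seed = cfg$seed)))
  sim <- simulate_panel(sc)
  write_sim(sim, cfg$input_prefix, cfg$dialect)
  say(cfg, "simulated ", sc$n_individuals, " individuals, ",
      nrow(sim$panel$markers), " markers")
  invisible(sim)
}

#' Fit the HBD model to a panel on disk
#'
#' Reads the panel, applies QC and the genetic map, fits every individual by
#' EM and writes `fit_results.tsv` (per sample: F, realized autozygosity per
#' class, loglik, EM iterations) and `fit_mixing.tsv` (per sample: fitted
#' mixing proportions) to the output directory.
#'
#' @param cfg a [run_config()].
#' @return The `hbd_panel_fit`, invisibly.
#' @export
run_fit <- function(cfg) {
  panel <- load_panel(cfg)
  model <- default_model(cfg$n_classes, cfg$eps)
  by_group <- !any(is.na(panel$samples$group)) &&
    length(unique(panel$samples$group)) > 1
  fit <- fit_hbd(panel, model, by_group = by_group)
  write_tsv(fit$results, out_path(cfg, "fit_results.tsv"))
  mix <- do.call(rbind, lapply(fit$fits, function(f) f$model$mixing))
  mix_df <- data.frame(sample_id = panel$samples$sample_id, mix,
                       check.names = FALSE, stringsAsFactors = FALSE)
  colnames(mix_df) <- c("sample_id", model$state_names)
  write_tsv(mix_df, out_path(cfg, "fit_mixing.tsv"))
  say(cfg, "fitted ", nrow(fit$results), " individuals; mean F = ",
      round(mean(fit$results$F), 4))
  invisible(fit)
}

#' Decode HBD segments for a fitted panel
#'
#' Reads the panel and the fitted mixing proportions written by [run_fit()],
#' Viterbi-decodes every individual and writes `segments.tsv` and
#' `segments.bed`.
#'
#' @param cfg a [run_config()].
#' @return The segment data.frame, invisibly.
#' @export
run_segments <- function(cfg) {
  mix_path <- out_path(cfg, "fit_mixing.tsv")
  if (!file.exists(mix_path))
    stop("missing expected file ", mix_path, "; run_fit must be executed first")
  panel <- load_panel(cfg)
  base <- default_model(cfg$n_classes, cfg$eps)
  mix <- read.table(mix_path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
  by_group <- !any(is.na(panel$samples$group)) &&
    length(unique(panel$samples$group)) > 1
  freqs <- allele_frequencies(panel, by_group = by_group)
  segs <- lapply(seq_len(nrow(panel$samples)), function(i) {
    id <- panel$samples$sample_id[i]
    row <- match(id, mix$sample_id)
    if (is.na(row)) stop("no fitted mixing for sample ", id)
    model_i <- hbd_model(base$rates, as.numeric(mix[row, -1]), base$eps)
    fr <- if (by_group) freqs[[panel$samples$group[i]]] else freqs
    v <- viterbi(panel$G[i, ], fr, panel$markers, model_i)
    path_to_segments(v$path, panel$markers, id, panel$samples$group[i], model_i)
  })
  segments <- do.call(rbind, segs)
  write_tsv(segments, out_path(cfg, "segments.tsv"))
  write_segments_bed(segments, out_path(cfg, "segments.bed"))
  say(cfg, nrow(segments), " HBD segments decoded")
  invisible(segments)
}

#' Summarise fit and segment outputs
#'
#' Reads `fit_results.tsv` and `segments.tsv` and writes the inbreeding
#' five-number summary per group (`inbreeding_summary.tsv`) and the per-class
#' / per-group segment summaries (`segments_by_class.tsv`,
#' `segments_by_group.tsv`).
#'
#' @param cfg a [run_config()].
#' @return List with `inbreeding` and `segments` summaries, invisibly.
#' @export
run_summarize <- function(cfg) {
  fit_path <- out_path(cfg, "fit_results.tsv")
  seg_path <- out_path(cfg, "segments.tsv")
  for (pth in c(fit_path, seg_path))
    if (!file.exists(pth))
      stop("missing expected file ", pth, "; run fit/segments first")
  res <- read.table(fit_path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
  segments <- read.table(seg_path, header = TRUE, sep = "\t",
                         check.names = FALSE, stringsAsFactors = FALSE)
  inb <- inbreeding_table(res$F, res$group)
  summ <- summarize_segments(segments,
                             data.frame(sample_id = res$sample_id,
                                        group = res$group,
                                        stringsAsFactors = FALSE))
  write_tsv(inb, out_path(cfg, "inbreeding_summary.tsv"))
  write_tsv(summ$by_class, out_path(cfg, "segments_by_class.tsv"))
  write_tsv(summ$by_group, out_path(cfg, "segments_by_group.tsv"))
  invisible(list(inbreeding = inb, segments = summ))
}

#' Overlap decoded segments with a feature BED file
#'
#' Reads `segments.tsv` and `cfg$features_bed` and writes
#' `overlap_per_segment.tsv`, `overlap_by_category.tsv` and
#' `overlap_by_chrom.tsv`.
#'
#' @param cfg a [run_config()] with `features_bed` set.
#' @return The overlap list from [overlap_segments()], invisibly.
#' @export
run_overlap <- function(cfg) {
  seg_path <- out_path(cfg, "segments.tsv")
  if (!file.exists(seg_path))
    stop("missing expected file ", seg_path, "; run_segments must be executed first")
  if (is.null(cfg$features_bed))
    stop("config error: features_bed is required for the overlap command")
  segments <- read.table(seg_path, header = TRUE, sep = "\t",
                         check.names = FALSE, stringsAsFactors = FALSE)
  ov <- overlap_segments(segments, read_features(cfg$features_bed))
  write_tsv(ov$per_segment, out_path(cfg, "overlap_per_segment.tsv"))
  write_tsv(ov$by_category, out_path(cfg, "overlap_by_category.tsv"))
  write_tsv(ov$by_chrom, out_path(cfg, "overlap_by_chrom.tsv"))
  invisible(ov)
}
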