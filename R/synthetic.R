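# Generative counterpart of the inference model: latent class paths sampled at
# marker resolution through the transition kernel, genotypes through the
# emission model, plus an outcross (F1-like) generator drawing one allele per
# parental frequency pool. Ground truth (state paths, segment terminations,
# occupancies, F) is recorded for recovery scoring.

#' Simulation configuration
#'
#' @param n_chrom number of chromosomes.
#' @param markers_per_chrom markers on each chromosome.
#' @param spacing_morgans uniform inter-marker distance in Morgans (default
#'   0.001, i.e. 0.1 cM — a dense livestock array).
#' @param freq_range bounds of the i.i.d. uniform coded-allele frequency
#'   distribution (default 0.05..0.95, keeping every marker informative).
#' @param model the true [hbd_model()] generating the latent paths.
#' @param n_individuals number of individuals.
#' @param seed RNG seed; the same seed reproduces the panel bit-identically.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_chrom = 10, markers_per_chrom = 1000,
                       spacing_morgans = 0.001, freq_range = c(0.05, 0.95),
                       model = default_model(), n_individuals = 20, seed = 1) {
  stopifnot(n_chrom >= 1, markers_per_chrom >= 1)
  if (spacing_morgans <= 0) stop("marker spacing must be positive")
  if (length(freq_range) != 2 || freq_range[1] <= 0 || freq_range[2] >= 1 ||
      freq_range[1] > freq_range[2])
    stop("freq_range bounds must lie within (0, 1)")
  structure(list(n_chrom = as.integer(n_chrom),
                 markers_per_chrom = as.integer(markers_per_chrom),
                 spacing_morgans = spacing_morgans, freq_range = freq_range,
                 model = model, n_individuals = as.integer(n_individuals),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# uniform marker map; physical positions at 1 Mb per cM for output realism
sim_map <- function(n_chrom, markers_per_chrom, spacing) {
  gpos_chr <- (seq_len(markers_per_chrom) - 1L) * spacing
  map <- data.frame(
    chrom = rep(as.character(seq_len(n_chrom)), each = markers_per_chrom),
    marker_id = paste0("snp_", rep(seq_len(n_chrom), each = markers_per_chrom),
                       "_", rep(seq_len(markers_per_chrom), n_chrom)),
    cm = 0,
    bp = rep(round(gpos_chr * 1e8) + 1, n_chrom),
    coded_allele = "A", other_allele = "B",
    gpos = rep(gpos_chr, n_chrom), stringsAsFactors = FALSE)
  map
}

# one chromosome's latent path: state_1 ~ mixing; between consecutive markers
# the segment survives w.p. exp(-R d), else terminates (a "break") and the new
# class is redrawn from mixing. Breaks are recorded even when the redrawn
# class equals the old one.
sim_path_chrom <- function(n, spacing, model) {
  S <- model$n_states
  stay <- exp(-model$rates * spacing)
  draws <- sample.int(S, n, replace = TRUE, prob = model$mixing)
  u <- runif(n)
  state <- integer(n)
  brk <- logical(n)
  state[1] <- draws[1]; brk[1] <- TRUE
  for (t in 2:n) {
    if (u[t] < stay[state[t - 1L]]) {
      state[t] <- state[t - 1L]
    } else {
      state[t] <- draws[t]; brk[t] <- TRUE
    }
  }
  list(state = state, brk = brk)
}

sim_genotypes <- function(state, p, model) {
  n <- length(state)
  hbd <- state < model$n_states
  hw <- rbinom(n, 2L, p)                      # Hardy-Weinberg draw
  ibd <- 2L * rbinom(n, 1L, p)                # one ancestral allele, doubled
  err <- runif(n) < model$eps
  g <- hw
  take_ibd <- hbd & !err
  g[take_ibd] <- ibd[take_ibd]
  g
}

#' Simulate a genotype panel from the HBD-class model
#'
#' Samples, per individual and chromosome, a latent class path through the
#' transition kernel at the configured marker spacing, then genotypes through
#' the emission model (HBD: one ancestral allele doubled; non-HBD:
#' Hardy-Weinberg; error rate eps redistributes to Hardy-Weinberg). Truth is
#' returned for recovery scoring: state paths, segment-termination indicators,
#' per-class occupancy fractions and true F.
#'
#' @param cfg a [sim_config()].
#' @return List with `panel` (a [genotype_panel()], group label `"sim"`),
#'   `truth` (list: `paths`, `breaks`, `occupancy` matrix, `F` vector) and
#'   `freqs` (the true allele frequencies).
#' @export
simulate_panel <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  model <- cfg$model
  map <- sim_map(cfg$n_chrom, cfg$markers_per_chrom, cfg$spacing_morgans)
  m <- nrow(map)
  p <- runif(m, cfg$freq_range[1], cfg$freq_range[2])
  S <- model$n_states
  G <- matrix(NA_integer_, cfg$n_individuals, m)
  paths <- breaks <- vector("list", cfg$n_individuals)
  occupancy <- matrix(0, cfg$n_individuals, S)
  colnames(occupancy) <- model$state_names
  chrom_idx <- split(seq_len(m), factor(map$chrom, levels = unique(map$chrom)))
  for (i in seq_len(cfg$n_individuals)) {
    state <- integer(m); brk <- logical(m)
    for (idx in chrom_idx) {
      r <- sim_path_chrom(length(idx), cfg$spacing_morgans, model)
      state[idx] <- r$state; brk[idx] <- r$brk
    }
    G[i, ] <- sim_genotypes(state, p, model)
    paths[[i]] <- state; breaks[[i]] <- brk
    occupancy[i, ] <- tabulate(state, nbins = S) / m
  }
  ids <- sprintf("sim_%03d", seq_len(cfg$n_individuals))
  samples <- data.frame(sample_id = ids, group = "sim", stringsAsFactors = FALSE)
  names(paths) <- names(breaks) <- rownames(occupancy) <- ids
  panel <- genotype_panel(G, map, samples)
  truth <- list(paths = paths, breaks = breaks, occupancy = occupancy,
                F = setNames(1 - occupancy[, S], ids))
  list(panel = panel, truth = truth, freqs = p)
}

#' True segment lengths from simulation truth
#'
#' Reconstructs the latent segments of one individual from the recorded
#' termination events and returns their genetic lengths, optionally excluding
#' segments censored by a chromosome end.
#'
#' @param truth the `truth` element of [simulate_panel()].
#' @param map the simulated marker map.
#' @param individual sample id or index.
#' @param drop_censored drop segments touching a chromosome boundary.
#' @return data.frame with `chrom`, `state`, `n_markers`, `length_morgans`
#'   (span between first and last marker of the segment).
#' @export
true_segment_lengths <- function(truth, map, individual = 1,
                                 drop_censored = TRUE) {
  state <- truth$paths[[individual]]
  brk <- truth$breaks[[individual]]
  chrom <- as.character(map$chrom)
  starts <- which(brk)
  ends <- c(starts[-1] - 1L, length(state))
  # right-censored: the segment ran into a chromosome end, its termination
  # was never observed
  censored <- ends == length(state) |
    chrom[ends] != chrom[pmin(ends + 1L, length(state))]
  out <- data.frame(chrom = chrom[starts], state = state[starts],
                    n_markers = ends - starts + 1L,
                    length_morgans = map$gpos[ends] - map$gpos[starts],
                    censored = censored, stringsAsFactors = FALSE)
  if (drop_censored) out <- out[!out$censored, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Simulate F1-like outcross individuals
#'
#' Each genotype is the sum of one allele drawn from pool A and one from pool
#' B, independently per marker — the offspring of two unrelated populations,
#' carrying no recent autozygosity.
#'
#' @param freqs_a,freqs_b coded-allele frequency vectors of the two parental
#'   pools (equal length).
#' @param n_individuals number of F1 individuals.
#' @param seed RNG seed.
#' @param map optional marker map; defaults to a uniform map matching
#'   [sim_config()] defaults (0.001 Morgan spacing, chromosomes of 1000
#'   markers).
#' @return A [genotype_panel()] with group label `"F1"`.
#' @export
simulate_outcross <- function(freqs_a, freqs_b, n_individuals, seed = 1,
                              map = NULL) {
  if (length(freqs_a) != length(freqs_b))
    stop("frequency vectors must have equal length")
  set.seed(seed)
  m <- length(freqs_a)
  if (is.null(map)) {
    per <- min(m, 1000L)
    if (m %% per != 0)
      map <- sim_map(1L, m, 0.001)
    else
      map <- sim_map(m %/% per, per, 0.001)
  }
  stopifnot(nrow(map) == m)
  G <- matrix(NA_integer_, n_individuals, m)
  for (i in seq_len(n_individuals))
    G[i, ] <- rbinom(m, 1L, freqs_a) + rbinom(m, 1L, freqs_b)
  ids <- sprintf("f1_%03d", seq_len(n_individuals))
  genotype_panel(G, map,
                 data.frame(sample_id = ids, group = "F1",
                            stringsAsFactors = FALSE))
}

#' Write a simulated panel and its truth to disk
#'
#' @param sim result of [simulate_panel()].
#' @param prefix output prefix; writes `<prefix>.ped`/`.map` (or the chosen
#'   dialect), `<prefix>_truth_states.tsv` (sample, marker, state) and
#'   `<prefix>_truth_summary.tsv` (sample, true_F, per-class occupancy).
#' @param dialect panel dialect passed to [write_panel()].
#' @return `prefix`, invisibly.
#' @export
write_sim <- function(sim, prefix, dialect = "ped") {
  write_panel(sim$panel, prefix, dialect)
  states <- do.call(rbind, lapply(names(sim$truth$paths), function(id)
    data.frame(sample_id = id, marker_id = sim$panel$markers$marker_id,
               state = sim$truth$paths[[id]], stringsAsFactors = FALSE)))
  write.table(states, paste0(prefix, "_truth_states.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  summ <- data.frame(sample_id = rownames(sim$truth$occupancy),
                     true_F = sim$truth$F, sim$truth$occupancy,
                     check.names = FALSE, row.names = NULL)
  write.table(summ, paste0(prefix, "_truth_summary.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(prefix)
}
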