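# Per-individual inference: scaled forward-backward (posterior decoding,
# realized autozygosity, F), EM over the class mixing proportions (rates stay
# fixed at the ladder), and Viterbi segment decoding. Chromosomes are
# independent: each restarts from the mixing distribution.

freqs_vec <- function(freqs, n_markers) {
  p <- if (is.data.frame(freqs)) freqs$p else as.numeric(freqs)
  if (length(p) != n_markers)
    stop("allele-frequency vector length (", length(p),
         ") does not match marker count (", n_markers, ")")
  p
}

map_gpos <- function(map) {
  gpos <- map$gpos
  if (is.null(gpos) || anyNA(gpos))
    stop("marker map has no genetic positions; run assign_gpos() first")
  gpos
}

# Precompute everything that stays fixed across EM iterations: per-chromosome
# emission blocks and inter-marker distances. The emission matrix depends only
# on genotypes, frequencies and eps, never on the mixing being estimated.
prepare_hmm <- function(genotypes, p, map, model) {
  gpos <- map_gpos(map)
  B <- emission_matrix(genotypes, p, model)
  idx_by_chrom <- split(seq_along(genotypes),
                        factor(map$chrom, levels = unique(map$chrom)))
  list(B = lapply(idx_by_chrom, function(idx) B[idx, , drop = FALSE]),
       E = lapply(idx_by_chrom, function(idx)
         exp(-outer(diff(gpos[idx]), model$rates))),
       idx = idx_by_chrom, n = length(genotypes),
       marker_id = map$marker_id)
}

# E-step over all chromosomes of one individual; returns gamma, loglik and the
# expected segment-start counts used by the EM M-step.
fb_pass <- function(prep, model) {
  S <- model$n_states
  gamma <- matrix(NA_real_, prep$n, S,
                  dimnames = list(prep$marker_id, model$state_names))
  loglik <- 0
  counts <- numeric(S)
  for (k in seq_along(prep$idx)) {
    idx <- prep$idx[[k]]
    if (length(idx) == 0L) { warning("empty chromosome skipped"); next }
    r <- fb_chrom_cpp(prep$B[[k]], prep$E[[k]], model$mixing)
    gamma[idx, ] <- r$gamma
    loglik <- loglik + r$loglik
    counts <- counts + r$start_counts + r$reset_counts
  }
  if (!is.finite(loglik)) stop("non-finite log-likelihood")
  list(gamma = gamma, loglik = loglik, counts = counts)
}

fb_individual <- function(genotypes, p, map, model) {
  fb_pass(prepare_hmm(genotypes, p, map, model), model)
}

#' Posterior decoding of one individual
#'
#' Runs the scaled forward-backward algorithm per chromosome (chromosomes are
#' independent; each starts from the mixing distribution) and summarises the
#' per-marker posterior state probabilities into realized autozygosity: the
#' genome-wide average posterior probability of each class. The inbreeding
#' coefficient is the summed realized autozygosity of all HBD classes, i.e.
#' 1 minus the non-HBD proportion.
#'
#' @param genotypes integer vector of coded-allele dosages (0/1/2/NA) for one
#'   individual, in marker-map order.
#' @param freqs allele frequencies: numeric vector or data.frame from
#'   [allele_frequencies()].
#' @param map marker map with `chrom` and `gpos` (Morgans; see
#'   [assign_gpos()]).
#' @param model an [hbd_model()].
#' @return An object of class `hbd_decoding`: list with `gamma` (markers x
#'   states posterior matrix), `loglik`, `realized` (per-state genome average)
#'   and `F`.
#' @export
forward_backward <- function(genotypes, freqs, map, model) {
  p <- freqs_vec(freqs, length(genotypes))
  r <- fb_individual(genotypes, p, map, model)
  realized <- colMeans(r$gamma)
  structure(list(gamma = r$gamma, loglik = r$loglik, realized = realized,
                 F = 1 - realized[[model$n_states]]),
            class = "hbd_decoding")
}

#' @export
print.hbd_decoding <- function(x, ...) {
  cat(sprintf("hbd_decoding: %d markers, loglik %.3f, F = %.4f\n",
              nrow(x$gamma), x$loglik, x$F))
  print(signif(x$realized, 4))
  invisible(x)
}

#' Fit class mixing proportions by EM
#'
#' The class rates stay fixed at their ladder; the free parameters are the
#' mixing proportions, estimated per individual. The M-step sets each class
#' frequency proportional to the expected number of segments started in that
#' class: chromosome-start occupancies plus expected segment-termination
#' (reset) events inside transitions. Treating the reset indicator as an
#' additional latent variable makes this an exact EM step, so the
#' log-likelihood is non-decreasing; a decrease beyond numerical noise raises
#' an error.
#'
#' @inheritParams forward_backward
#' @param max_iter maximum number of EM updates.
#' @param tol stop when the absolute log-likelihood change drops below `tol`.
#' @return List of class `hbd_fit`: `model` (fitted), `decoding`
#'   (an `hbd_decoding` under the fitted model), `loglik_trace`, `n_iter`,
#'   `converged`.
#' @export
em_fit <- function(genotypes, freqs, map, model, max_iter = 1000, tol = 1e-6) {
  p <- freqs_vec(freqs, length(genotypes))
  prep <- prepare_hmm(genotypes, p, map, model)
  trace <- numeric(0)
  last <- NA_real_
  converged <- FALSE
  n_iter <- 0L
  for (it in 0:max_iter) {
    e <- fb_pass(prep, model)
    if (!is.na(last) && e$loglik < last - 1e-6)
      stop(sprintf("EM log-likelihood decreased (%.9g -> %.9g)", last, e$loglik))
    trace <- c(trace, e$loglik)
    if (!is.na(last) && abs(e$loglik - last) < tol) { converged <- TRUE; break }
    if (it == max_iter) break
    last <- e$loglik
    mix <- e$counts / sum(e$counts)
    model <- hbd_model(model$rates, mix, model$eps)
    n_iter <- it + 1L
  }
  realized <- colMeans(e$gamma)
  decoding <- structure(list(gamma = e$gamma, loglik = e$loglik,
                             realized = realized,
                             F = 1 - realized[[model$n_states]]),
                        class = "hbd_decoding")
  structure(list(model = model, decoding = decoding, loglik_trace = trace,
                 n_iter = n_iter, converged = converged),
            class = "hbd_fit")
}

#' Viterbi decoding of one individual
#'
#' Log-space max-product recursion per chromosome with backtracking; ties are
#' broken toward the lowest state index, i.e. the most recent HBD class.
#'
#' @inheritParams forward_backward
#' @return List with `path` (integer state per marker; HBD classes
#'   1..n_states-1, non-HBD = n_states) and `logp`, the log joint probability
#'   of the best path (summed over chromosomes).
#' @export
viterbi <- function(genotypes, freqs, map, model) {
  p <- freqs_vec(freqs, length(genotypes))
  gpos <- map_gpos(map)
  B <- emission_matrix(genotypes, p, model)
  idx_by_chrom <- split(seq_along(genotypes), factor(map$chrom, levels = unique(map$chrom)))
  path <- integer(length(genotypes))
  logp <- 0
  for (idx in idx_by_chrom) {
    r <- viterbi_chrom_cpp(B[idx, , drop = FALSE], diff(gpos[idx]),
                           model$rates, model$mixing)
    path[idx] <- r$path
    logp <- logp + r$logp
  }
  if (!is.finite(logp)) stop("non-finite Viterbi path probability")
  list(path = path, logp = logp)
}

#' Fit every individual of a panel
#'
#' Convenience driver: computes allele frequencies (within each analysis group
#' by default), fits the mixing proportions of each individual by EM and
#' collects inbreeding coefficients and realized autozygosity.
#'
#' @param panel a [genotype_panel()] whose map carries genetic positions.
#' @param model starting [hbd_model()] shared by all individuals.
#' @param by_group compute allele frequencies within each group (`TRUE`) or
#'   pooled.
#' @param max_iter,tol EM controls, as in [em_fit()].
#' @return List of class `hbd_panel_fit`: `results` (data.frame with one row
#'   per sample: `sample_id`, `group`, `loglik`, `n_iter`, `F` and one
#'   realized-autozygosity column per state), `fits` (per-sample `hbd_fit`
#'   objects) and `freqs`.
#' @export
fit_hbd <- function(panel, model = default_model(), by_group = TRUE,
                    max_iter = 1000, tol = 1e-6) {
  freqs <- allele_frequencies(panel, by_group = by_group)
  n <- nrow(panel$samples)
  fits <- vector("list", n)
  names(fits) <- panel$samples$sample_id
  realized <- matrix(NA_real_, n, model$n_states,
                     dimnames = list(panel$samples$sample_id, model$state_names))
  Fvec <- loglik <- numeric(n)
  n_iter <- integer(n)
  for (i in seq_len(n)) {
    fr <- if (by_group) freqs[[panel$samples$group[i]]] else freqs
    fit <- em_fit(panel$G[i, ], fr, panel$markers, model,
                  max_iter = max_iter, tol = tol)
    fits[[i]] <- fit
    realized[i, ] <- fit$decoding$realized
    Fvec[i] <- fit$decoding$F
    loglik[i] <- fit$decoding$loglik
    n_iter[i] <- fit$n_iter
  }
  results <- data.frame(sample_id = panel$samples$sample_id,
                        group = panel$samples$group,
                        loglik = loglik, n_iter = n_iter, F = Fvec,
                        realized, check.names = FALSE,
                        row.names = NULL, stringsAsFactors = FALSE)
  structure(list(results = results, fits = fits, freqs = freqs, model = model),
            class = "hbd_panel_fit")
}

#' Stationary state occupancy of a model
#'
#' The long-run fraction of the genome occupied by each class: segments of
#' class c start with probability m_c and last 1/R_c Morgans on average, so
#' occupancy is proportional to m_c / R_c.
#'
#' @param model an [hbd_model()].
#' @return Named numeric vector summing to 1; `1 - occ["nonHBD"]` is the
#'   expected inbreeding coefficient of the model.
#' @export
stationary_occupancy <- function(model) {
  occ <- model$mixing / model$rates
  setNames(occ / sum(occ), model$state_names)
}

#' Mixing proportions that yield a target genome occupancy
#'
#' Inverse of [stationary_occupancy()]: given the desired long-run genome
#' fraction of each class, returns the mixing vector (m proportional to
#' occupancy times rate).
#'
#' @param occupancy non-negative vector, one entry per state, summing to 1.
#' @param rates class rates, one per state.
#' @return Mixing vector on the simplex.
#' @export
mixing_for_occupancy <- function(occupancy, rates) {
  if (length(occupancy) != length(rates))
    stop("occupancy and rates must have the same length")
  if (any(occupancy < 0) || abs(sum(occupancy) - 1) > 1e-8)
    stop("occupancy must be non-negative and sum to 1")
  m <- occupancy * rates
  m / sum(m)
}
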