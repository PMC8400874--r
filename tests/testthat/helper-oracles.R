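# Independent brute-force oracles used across the suite. These deliberately
# share no code with the package's recursions.

# Exhaustive enumeration over all state sequences of a small HMM instance.
# B: markers x states emission likelihoods; d: inter-marker Morgans.
brute_force_decode <- function(B, d, rates, mixing) {
  n <- nrow(B); S <- ncol(B)
  A <- lapply(d, function(dd) {
    e <- exp(-rates * dd)
    diag(e, S) + (1 - e) %o% mixing
  })
  seqs <- as.matrix(expand.grid(rep(list(seq_len(S)), n)))
  total <- 0; best <- -Inf; best_path <- NULL
  for (r in seq_len(nrow(seqs))) {
    s <- seqs[r, ]
    pr <- mixing[s[1]] * B[1, s[1]]
    if (n > 1) for (t in 2:n) pr <- pr * A[[t - 1]][s[t - 1], s[t]] * B[t, s[t]]
    total <- total + pr
    if (pr > best) { best <- pr; best_path <- s }
  }
  list(loglik = log(total), best_logp = log(best), best_path = unname(best_path))
}

# emission matrix assembled marker-by-marker through the exported scalar op
emission_B <- function(genotypes, p, eps, n_states) {
  t(vapply(seq_along(genotypes),
           function(j) emission_probs(genotypes[j], p[j], eps, n_states),
           numeric(n_states)))
}

# run-length scan: one pass, no vectorised tricks
rle_hbd_runs <- function(path, chrom, n_states) {
  runs <- list()
  start <- 1L
  for (t in seq_along(path)) {
    last <- t == length(path)
    boundary <- last || path[t + 1] != path[t] || chrom[t + 1] != chrom[t]
    if (boundary) {
      if (path[t] < n_states)
        runs[[length(runs) + 1L]] <- c(state = path[t], start = start, end = t)
      start <- t + 1L
    }
  }
  do.call(rbind, runs)
}

# quartiles by linear interpolation (type 7), written out longhand
q7 <- function(x, p) {
  x <- sort(x); n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# quadratic all-pairs interval intersection; segments 1-based inclusive,
# features 0-based half-open
quadratic_overlap <- function(segments, features) {
  hits <- NULL
  for (i in seq_len(nrow(segments))) for (j in seq_len(nrow(features))) {
    if (segments$chrom[i] != features$chrom[j]) next
    s <- segments$start_bp[i] - 1; e <- segments$end_bp[i]
    if (max(s, features$start[j]) < min(e, features$end[j]))
      hits <- rbind(hits, c(seg = i, feat = j))
  }
  hits
}
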