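# Small in-code fixtures shared by the I/O and pipeline tests.

make_markers <- function(n, chrom = "1", bp = NULL, spacing_m = 0.001) {
  if (is.null(bp)) bp <- seq_len(n) * 100000
  data.frame(chrom = rep(chrom, length.out = n),
             marker_id = paste0("m", seq_len(n)), cm = 0, bp = bp,
             coded_allele = "A", other_allele = "B",
             gpos = (seq_len(n) - 1) * spacing_m, stringsAsFactors = FALSE)
}

make_panel <- function(G, chrom = "1", groups = NULL) {
  n <- nrow(G); m <- ncol(G)
  samples <- data.frame(sample_id = paste0("s", seq_len(n)),
                        group = if (is.null(groups)) rep("grp", n) else groups,
                        stringsAsFactors = FALSE)
  genotype_panel(G, make_markers(m, chrom = chrom), samples)
}

random_panel <- function(n_samples, n_markers, miss = 0.05, seed = 1) {
  set.seed(seed)
  G <- matrix(sample(0:2, n_samples * n_markers, replace = TRUE),
              n_samples, n_markers)
  G[runif(length(G)) < miss] <- NA_integer_
  make_panel(G)
}
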