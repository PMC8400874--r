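test_that("state paths decompose into maximal single-class HBD runs", {
  model <- hbd_model(c(2, 4, 4), rep(1 / 3, 3))
  map <- make_markers(4)
  segs <- path_to_segments(c(1L, 1L, 3L, 1L), map, "s1", "g", model)
  expect_equal(nrow(segs), 2L)
  expect_equal(segs$class_rate, c(2, 2))
  expect_equal(segs$n_snps, c(2L, 1L))
  expect_equal(segs$start_bp, c(100000, 400000))
  expect_equal(segs$end_bp, c(200000, 400000))
  expect_equal(segs$length_mb, c(0.1, 0))

  none <- path_to_segments(rep(3L, 4), map, "s1", "g", model)
  expect_equal(nrow(none), 0L)
  expect_error(path_to_segments(c(1L, 2L), map, "s1", "g", model), "length")
})

test_that("segments equal a brute-force run-length scan on random paths", {
  model <- default_model()
  set.seed(17)
  n <- 200
  map <- make_markers(n, chrom = rep(c("1", "2"), each = 100))
  path <- sample(1:10, n, replace = TRUE, prob = c(rep(0.04, 9), 0.64))
  segs <- path_to_segments(path, map, "s1", "g", model)
  oracle <- rle_hbd_runs(path, as.character(map$chrom), model$n_states)
  expect_equal(nrow(segs), nrow(oracle))
  expect_equal(segs$class_rate, model$rates[oracle[, "state"]])
  expect_equal(segs$start_bp, map$bp[oracle[, "start"]])
  expect_equal(segs$end_bp, map$bp[oracle[, "end"]])
  expect_equal(segs$n_snps, unname(oracle[, "end"] - oracle[, "start"] + 1L))
  # total SNPs in segments equals markers assigned to HBD states
  expect_equal(sum(segs$n_snps), sum(path < 10))
  # no segment crosses the chromosome boundary
  expect_true(all(segs$end_bp >= segs$start_bp))
  expect_true(all((oracle[, "start"] > 100) == (oracle[, "end"] > 100)))
})

test_that("per-group summaries match hand computation", {
  model <- hbd_model(c(2, 2), c(0.5, 0.5))
  segs <- data.frame(sample_id = "s1", group = "g", chrom = "1",
                     class_rate = 2, start_bp = c(1, 1), end_bp = c(1000001, 3000001),
                     n_snps = c(10L, 30L), length_mb = c(1, 3),
                     length_morgans = c(0.01, 0.03), stringsAsFactors = FALSE)
  samples <- data.frame(sample_id = "s1", group = "g", stringsAsFactors = FALSE)
  s <- summarize_segments(segs, samples)
  expect_equal(s$by_class$n, 2L)
  expect_equal(s$by_class$mean_length_mb, 2)
  expect_equal(s$by_class$se_length_mb, sd(c(1, 3)) / sqrt(2))  # = 1
  expect_equal(s$by_class$se_length_mb, 1)
  expect_equal(s$by_group$segments_per_animal, 2)

  empty <- summarize_segments(segs[0, ], samples)
  expect_equal(empty$by_group$n_segments, 0L)
  expect_true(is.nan(empty$by_group$mean_length_mb))

  # two groups, one animal each: per-animal average is each group's own count
  segs2 <- rbind(segs, within(segs, { sample_id <- "s2"; group <- "h" }))
  samples2 <- data.frame(sample_id = c("s1", "s2"), group = c("g", "h"))
  s2 <- summarize_segments(segs2, samples2)
  expect_equal(s2$by_group$segments_per_animal, c(2, 2))

  # permutation invariance of the counts
  s3 <- summarize_segments(segs2[sample(nrow(segs2)), ], samples2)
  expect_equal(s3$by_class, s2$by_class)

  expect_error(summarize_segments(within(segs, group <- "zz"), samples),
               "group label")
})

test_that("longest-segment ranking and per-chromosome tallies are correct", {
  set.seed(23)
  n <- 100
  segs <- data.frame(sample_id = "s1",
                     group = sample(c("A", "B"), n, TRUE),
                     chrom = as.character(sample(1:5, n, TRUE)),
                     class_rate = sample(c(2, 4, 128), n, TRUE),
                     start_bp = sample.int(1e6, n), stringsAsFactors = FALSE)
  segs$end_bp <- segs$start_bp + sample.int(9e6, n)
  segs$n_snps <- 10L
  segs$length_mb <- (segs$end_bp - segs$start_bp) / 1e6
  segs$length_morgans <- segs$length_mb / 100

  simple <- data.frame(sample_id = "s", group = "A", chrom = "1",
                       class_rate = 2, start_bp = 1,
                       end_bp = c(5e6, 9e6, 2e6) + 1, n_snps = 5L,
                       length_mb = c(5, 9, 2), length_morgans = 0.01)
  top <- longest_segments(simple, classes = 2, top_n = 2)
  expect_equal(top$top$length_mb, c(9, 5))
  expect_equal(nrow(longest_segments(simple, classes = 64)$top), 0L)

  res <- longest_segments(segs, classes = c(2, 4), top_n = 10)
  sel <- segs[segs$class_rate %in% c(2, 4), ]
  expect_equal(res$top$length_mb, sort(sel$length_mb, decreasing = TRUE)[1:10])
  for (r in seq_len(nrow(res$by_chrom))) {
    expect_equal(res$by_chrom$n[r],
                 sum(sel$chrom == res$by_chrom$chrom[r] &
                       sel$group == res$by_chrom$group[r]))
  }
  expect_error(longest_segments(segs, classes = numeric(0)), "non-empty")
})

test_that("inbreeding summary matches an independent quantile computation", {
  tab <- inbreeding_table(c(0.1, 0.2, 0.3), rep("g", 3))
  expect_equal(tab$min, 0.1)
  expect_equal(tab$median, 0.2)
  expect_equal(tab$mean, 0.2)
  expect_equal(tab$max, 0.3)

  one <- inbreeding_table(0.42, "g")
  expect_equal(unlist(one[c("min", "q1", "median", "mean", "q3", "max")]),
               rep(0.42, 6), ignore_attr = TRUE)

  set.seed(31)
  x <- runif(50, 0, 0.5)
  tab2 <- inbreeding_table(x, rep("g", 50))
  expect_equal(tab2$q1, q7(x, 0.25))
  expect_equal(tab2$median, q7(x, 0.5))
  expect_equal(tab2$q3, q7(x, 0.75))

  expect_error(inbreeding_table(numeric(0), character(0)), "empty group")
})
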