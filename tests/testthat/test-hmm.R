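# random small instances shared by the enumeration-oracle tests
random_instance <- function(seed) {
  set.seed(seed)
  n <- sample(2:8, 1)
  S <- sample(2:3, 1)
  rates <- sort(exp(runif(S, log(1), log(200))))
  mixing <- as.numeric(prop.table(runif(S) + 0.05))
  model <- hbd_model(rates, mixing, eps = runif(1, 0, 0.05))
  p <- runif(n, 0.05, 0.95)
  g <- sample(c(0:2, NA), n, replace = TRUE)
  map <- make_markers(n)
  map$gpos <- cumsum(c(0, runif(n - 1, 1e-4, 0.05)))
  list(model = model, p = p, g = g, map = map)
}

test_that("forward log-likelihood equals exhaustive enumeration", {
  for (seed in 1:12) {
    inst <- random_instance(seed)
    dec <- forward_backward(inst$g, inst$p, inst$map, inst$model)
    B <- emission_B(inst$g, inst$p, inst$model$eps, inst$model$n_states)
    oracle <- brute_force_decode(B, diff(inst$map$gpos), inst$model$rates,
                                 inst$model$mixing)
    expect_equal(dec$loglik, oracle$loglik, tolerance = 1e-10)
  }
})

test_that("Viterbi best-path probability equals exhaustive enumeration", {
  for (seed in 101:112) {
    inst <- random_instance(seed)
    v <- viterbi(inst$g, inst$p, inst$map, inst$model)
    B <- emission_B(inst$g, inst$p, inst$model$eps, inst$model$n_states)
    oracle <- brute_force_decode(B, diff(inst$map$gpos), inst$model$rates,
                                 inst$model$mixing)
    expect_equal(v$logp, oracle$best_logp, tolerance = 1e-10)
    expect_equal(v$path, oracle$best_path)
  }
})

test_that("posteriors are proper distributions and F complements non-HBD", {
  cfg <- sim_config(n_chrom = 3, markers_per_chrom = 300, n_individuals = 2,
                    seed = 21)
  sim <- simulate_panel(cfg)
  fr <- allele_frequencies(sim$panel)
  dec <- forward_backward(sim$panel$G[1, ], fr, sim$panel$markers, cfg$model)
  expect_equal(unname(rowSums(dec$gamma)), rep(1, nrow(dec$gamma)),
               tolerance = 1e-8)
  expect_equal(sum(dec$realized), 1, tolerance = 1e-8)
  expect_true(dec$F >= 0 && dec$F <= 1)
  expect_identical(dec$F, 1 - dec$realized[["nonHBD"]])
})

test_that("with all genotypes missing the posterior is the prior marginal", {
  model <- hbd_model(c(2, 8, 8), c(0.2, 0.3, 0.5), eps = 0.001)
  n <- 15
  map <- make_markers(n, spacing_m = 0.02)
  g <- rep(NA_integer_, n)
  dec <- forward_backward(g, runif(n, 0.1, 0.9), map, model)
  mu <- model$mixing
  for (t in seq_len(n)) {
    expect_equal(unname(dec$gamma[t, ]), mu, tolerance = 1e-12)
    mu <- as.numeric(t(transition_matrix(0.02, model)) %*% mu)
  }
  # Viterbi with uninformative emissions sits in the a-priori dominant state
  model2 <- hbd_model(c(2, 2), c(0.3, 0.7), eps = 0.001)
  v <- viterbi(rep(NA_integer_, 20), rep(0.5, 20), make_markers(20), model2)
  expect_equal(v$path, rep(2L, 20))
})

test_that("EM recovers a planted two-state mixing within 0.1", {
  model_true <- hbd_model(c(2, 2), c(0.3, 0.7), eps = 0.001)
  cfg <- sim_config(n_chrom = 5, markers_per_chrom = 1000,
                    model = model_true, n_individuals = 1, seed = 33)
  sim <- simulate_panel(cfg)
  fit <- em_fit(sim$panel$G[1, ], sim$freqs, sim$panel$markers,
                hbd_model(c(2, 2), c(0.5, 0.5), eps = 0.001))
  expect_lt(abs(fit$model$mixing[1] - 0.3), 0.1)
  expect_lt(abs(fit$model$mixing[2] - 0.7), 0.1)
})

test_that("EM log-likelihood is monotone and honours its stopping rules", {
  cfg <- sim_config(n_chrom = 2, markers_per_chrom = 400, n_individuals = 1,
                    seed = 44)
  sim <- simulate_panel(cfg)
  fr <- allele_frequencies(sim$panel)
  fit <- em_fit(sim$panel$G[1, ], fr, sim$panel$markers, cfg$model,
                max_iter = 50)
  expect_true(all(diff(fit$loglik_trace) > -1e-9))

  # starting at the generating parameters one update cannot hurt
  fit1 <- em_fit(sim$panel$G[1, ], fr, sim$panel$markers, cfg$model,
                 max_iter = 1)
  expect_true(all(diff(fit1$loglik_trace) > -1e-9))

  # tol = Inf stops after a single update with a finite log-likelihood
  fit_inf <- em_fit(sim$panel$G[1, ], fr, sim$panel$markers, cfg$model,
                    tol = Inf)
  expect_equal(fit_inf$n_iter, 1L)
  expect_true(is.finite(fit_inf$decoding$loglik))
})

test_that("fully homozygous stretches decode as HBD", {
  model <- hbd_model(c(4, 4), c(0.5, 0.5), eps = 0)
  n <- 60
  map <- make_markers(n, spacing_m = 0.01)
  p <- rep(0.5, n)
  set.seed(8)
  g <- 2L * rbinom(n, 1, 0.5)                  # homozygous at informative markers
  v <- viterbi(g, p, map, model)
  expect_true(all(v$path == 1L))
})

test_that("splitting a chromosome changes the log-likelihood only marginally", {
  cfg <- sim_config(n_chrom = 1, markers_per_chrom = 1000, n_individuals = 1,
                    seed = 55)
  sim <- simulate_panel(cfg)
  fr <- allele_frequencies(sim$panel)
  dec1 <- forward_backward(sim$panel$G[1, ], fr, sim$panel$markers, cfg$model)
  map_split <- sim$panel$markers
  map_split$chrom[501:1000] <- "1b"
  dec2 <- forward_backward(sim$panel$G[1, ], fr, map_split, cfg$model)
  expect_lt(abs(dec1$loglik - dec2$loglik), 10)
  expect_lt(abs(dec1$loglik - dec2$loglik) / abs(dec1$loglik), 0.05)
})

test_that("occupancy-mixing conversions are mutually inverse", {
  m <- default_model()
  occ <- stationary_occupancy(m)
  expect_equal(sum(occ), 1)
  expect_equal(unname(mixing_for_occupancy(occ, m$rates)), m$mixing)
  mix <- mixing_for_occupancy(c(rep(0.25 / 9, 9), 0.75), m$rates)
  m2 <- hbd_model(m$rates, mix)
  expect_equal(unname(1 - stationary_occupancy(m2)[["nonHBD"]]), 0.25)
})
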