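test_that("saturating encoder evaluates the sigmoidal duration-rate curve", {
  enc <- make_saturating_encoder(r_max = 100, s_half = 0.2, slope = 4,
                                 r0 = 5, window = 0.15)
  expect_equal(enc$mu(0.2), 0.15 * 55)
  expect_equal(enc$mu(-50), 0.15 * 5, tolerance = 1e-10)  # s -> -Inf limit
  expect_true(all(diff(enc$mu(seq(-1, 2, by = 0.05))) > 0))

  flat <- make_saturating_encoder(r_max = 100, s_half = 0.2, slope = 0,
                                  r0 = 5, window = 0.15)
  expect_equal(flat$mu(c(-1, 0, 1)), rep(0.15 * 55, 3))
  expect_equal(analytic_fisher(flat, 0.3), 0)  # constant mean carries no info
})

test_that("Jeffreys-matched encoder has Fisher information c^2 f^2 exactly", {
  b <- bounds8()
  enc <- make_jeffreys_matched_encoder(b, mu_min = 1, c_scale = 1)
  s <- seq(log10(b$tau), log10(b$T_B), length.out = 201)
  expect_equal(analytic_fisher(enc, s), log_blank_density(s, b)^2,
               tolerance = 1e-10)
  expect_equal(analytic_fisher(enc, 0), 2.619603, tolerance = 1e-5)

  # sqrt(F), normalized to a density, is the log-blank density itself
  sqrtF <- sqrt(analytic_fisher(enc, s))
  norm <- stats::integrate(function(z) sqrt(analytic_fisher(enc, z)),
                           s[1], s[length(s)], rel.tol = 1e-10)$value
  expect_equal(sqrtF / norm, log_blank_density(s, b), tolerance = 1e-6)

  none <- make_jeffreys_matched_encoder(b, mu_min = 1, c_scale = 0)
  expect_equal(analytic_fisher(none, s), rep(0, length(s)))
})

test_that("analytic Fisher information covers both noise families", {
  # Poisson with mu = e^s: F = (e^s)^2 / e^s = e^s
  exp_enc <- plumecoding:::new_encoder(mu = exp, mu_prime = exp,
                                       noise = "poisson", sigma2 = NULL,
                                       theta = 0, r0 = 0, window = 0.15,
                                       label = "test")
  expect_equal(analytic_fisher(exp_enc, c(0, 1, 2)), exp(c(0, 1, 2)))
  # Gaussian with mu = 2s, sigma2 = 4: F = 4/4 = 1
  lin_enc <- plumecoding:::new_encoder(mu = function(s) 2 * s,
                                       mu_prime = function(s) rep(2, length(s)),
                                       noise = "gaussian",
                                       sigma2 = function(s) rep(4, length(s)),
                                       theta = 0, r0 = 0, window = 0.15,
                                       label = "test")
  expect_equal(analytic_fisher(lin_enc, c(0.5, 1)), c(1, 1))
})

test_that("simulated window counts honor the encoder mean and noise family", {
  # fixed preceding blank of 2 s -> every response is drawn at s = log10(2)
  sq <- fixed_sequence(blank_dur = 2, whiff_dur = 1.5, n_pairs = 4000)
  enc <- make_saturating_encoder(r_max = 60, s_half = 0.2, slope = 3,
                                 r0 = 0, theta = 0.02, window = 0.15)
  rec <- simulate_recording(enc, sq, seed = 101L)
  samples <- extract_responses(rec, theta = 0.02, analysis_start = 0,
                               analysis_end = sq$total_duration)
  expect_gt(nrow(samples), 3500)
  mu <- enc$mu(log10(2))
  se <- stats::sd(samples$r) / sqrt(nrow(samples))
  expect_lt(abs(mean(samples$r) - mu), 3 * se)
  # Poisson counts: variance tracks the mean
  expect_equal(stats::var(samples$r), mu, tolerance = 0.1)
})

test_that("response spikes respect the injected latency when r0 = 0", {
  sq <- fixed_sequence(blank_dur = 2, whiff_dur = 1.5, n_pairs = 200)
  enc <- make_saturating_encoder(r_max = 80, s_half = 0, slope = 2,
                                 r0 = 0, theta = 0.026, window = 0.15)
  rec <- simulate_recording(enc, sq, seed = 7L)
  onsets <- sq$events$onset[sq$events$kind == "whiff"]
  for (on in onsets[1:50]) {
    after <- rec$spikes[rec$spikes > on][1]
    if (!is.na(after) && after < on + 1.5) {
      expect_gte(after - on, 0.026)
    }
  }
})

test_that("silent encoders give empty spike trains; seeds reproduce exactly", {
  sq <- fixed_sequence(2, 1.5, 10)
  silent <- make_saturating_encoder(r_max = 1e-12, s_half = 0, slope = 1,
                                    r0 = 0)
  expect_length(simulate_recording(silent, sq, seed = 1L)$spikes, 0)

  enc <- make_saturating_encoder(r_max = 50, s_half = 0.2, slope = 3, r0 = 10)
  expect_identical(simulate_recording(enc, sq, seed = 5L)$spikes,
                   simulate_recording(enc, sq, seed = 5L)$spikes)
})

test_that("population simulation yields distinct, reproducible recordings", {
  p <- plume_params(d = 16)
  enc <- make_jeffreys_matched_encoder(derive_timescales(p))
  pop <- simulate_population(enc, p, n_neurons = 5, duration_s = 120,
                             seed = 31L, dose = 1e-2)
  expect_length(pop, 5)
  seq_seeds <- vapply(pop, function(r) r$sequence$seed, integer(1))
  expect_equal(length(unique(seq_seeds)), 5)  # each neuron gets its own plume
  pop2 <- simulate_population(enc, p, n_neurons = 5, duration_s = 120,
                              seed = 31L, dose = 1e-2)
  expect_identical(lapply(pop, `[[`, "spikes"), lapply(pop2, `[[`, "spikes"))

  # pooled response count tracks n_neurons x expected whiff pairs
  b <- derive_timescales(p)
  samples <- pool_samples(pop, theta = 0.026, analysis_start = 0,
                          analysis_end = 120)
  expect_equal(nrow(samples), 5 * expected_whiff_pairs(b, 120),
               tolerance = 0.35)
})

test_that("adaptation gain decays towards the stationary response", {
  sq <- fixed_sequence(2, 1.5, 600)
  enc <- make_saturating_encoder(r_max = 60, s_half = 0.2, slope = 3,
                                 r0 = 0, theta = 0, window = 0.15)
  rec <- simulate_recording(enc, sq, seed = 13L,
                            adaptation = list(gain0 = 3, tau = 50))
  samples <- extract_responses(rec, theta = 0, analysis_start = 0,
                               analysis_end = sq$total_duration)
  early <- samples$r[samples$onset < 50]
  late <- samples$r[samples$onset > 500]
  expect_gt(mean(early), 1.5 * mean(late))
  expect_equal(mean(late), enc$mu(log10(2)), tolerance = 0.15)
})
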