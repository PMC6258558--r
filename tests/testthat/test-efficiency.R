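test_that("Fisher profile is the squared slope over the variance", {
  # gamma = 2s + 1, sigma2 = 4 -> F identically 1
  fit <- fit_from_functions(function(s) 2 * s + 1,
                            function(s) rep(2, length(s)),
                            function(s) rep(4, length(s)), c(0, 1))
  prof <- fisher_profile(fit)
  expect_equal(prof$F, rep(1, 201))

  flat <- fit_from_functions(function(s) rep(3, length(s)),
                             function(s) rep(0, length(s)),
                             function(s) rep(2, length(s)), c(0, 1))
  expect_equal(fisher_profile(flat)$F, rep(0, 201))

  bad <- fit_from_functions(function(s) s, function(s) rep(1, length(s)),
                            function(s) rep(-1, length(s)), c(0, 1))
  expect_error(fisher_profile(bad), "positive")
})

test_that("profile normalization scales to unit maximum and is idempotent", {
  prof <- profile_from_values(seq(0, 1, length.out = 101),
                              exp(-seq(0, 1, length.out = 101)))
  np <- normalize_profile(prof)
  expect_equal(max(np$F), 1)
  expect_equal(np$mode, prof$mode)
  expect_equal(normalize_profile(np)$F, np$F)
  expect_equal(normalize_profile(profile_from_values(0:1, c(2, 2)))$F, c(1, 1))
  expect_error(normalize_profile(profile_from_values(0:1, c(0, 0))),
               "all-zero")
})

test_that("average Fisher information integrates against the blank density", {
  for (d in c(8, 16, 32, 64, 128)) {
    b <- derive_timescales(plume_params(d = d))
    grid <- seq(log10(b$tau), log10(b$T_B), length.out = 201)
    unit <- profile_from_values(grid, rep(1, 201))
    expect_equal(average_fisher(unit, b), 1, tolerance = 1e-6)
    expect_equal(average_fisher(profile_from_values(grid, rep(0, 201)), b), 0)
  }

  # oracle: <F> for F = f_log10B itself is the integral of f^2
  b <- bounds8()
  grid <- seq(0, log10(12), length.out = 2001)
  prof <- profile_from_values(grid, log_blank_density(grid, b))
  oracle <- stats::integrate(function(s) log_blank_density(s, b)^2, 0,
                             log10(12), rel.tol = 1e-10)$value
  expect_equal(oracle, 1.042872, tolerance = 1e-6)
  expect_equal(average_fisher(prof, b), oracle, tolerance = 1e-5)

  # uncovered blank range is refused by name
  b128 <- derive_timescales(plume_params(d = 128))
  expect_error(average_fisher(prof, b128), "does not cover")
})

test_that("average Fisher information is bounded by the profile extremes", {
  b <- derive_timescales(plume_params(d = 16))
  grid <- seq(log10(b$tau), log10(b$T_B), length.out = 201)
  set.seed(91)
  for (i in 1:10) {
    F_val <- stats::runif(201, 0, 10)
    avg <- average_fisher(profile_from_values(grid, F_val), b)
    expect_gte(avg, min(F_val))
    expect_lte(avg, max(F_val))
  }
})

test_that("matched-vs-mismatched tables agree with quadrature and stay triangular", {
  dists <- c(8, 16, 32)
  bnds <- lapply(dists, function(d) derive_timescales(plume_params(d = d)))
  names(bnds) <- dists
  # analytic f^2-shaped profiles (the Jeffreys-matched construction)
  profs <- lapply(bnds, function(b) {
    grid <- seq(log10(b$tau), log10(b$T_B), length.out = 2001)
    profile_from_values(grid, log_blank_density(grid, b)^2)
  })
  res <- matched_vs_mismatched(profs, bnds)
  expect_true(all(is.na(res$table[upper.tri(res$table)])))
  for (i in seq_along(dists)) {
    for (j in seq_len(i)) {
      oracle <- stats::integrate(function(s) {
        log_blank_density(s, bnds[[i]])^2 * log_blank_density(s, bnds[[j]])
      }, log10(bnds[[j]]$tau), log10(bnds[[j]]$T_B), rel.tol = 1e-10)$value
      expect_equal(res$table[i, j], oracle, tolerance = 1e-4)
    }
  }
  # a single distance is trivially matched-best
  one <- matched_vs_mismatched(profs["8"], bnds["8"])
  expect_true(one$matched_best)
  expect_equal(dim(one$table), c(1, 1))
})

test_that("the log-blank median has its closed form and grows with distance", {
  expect_equal(median_log_blank(bounds8()), 0.3817731, tolerance = 1e-6)
  meds <- vapply(c(8, 16, 32, 64, 128), function(d) {
    median_log_blank(derive_timescales(plume_params(d = d)))
  }, numeric(1))
  expect_true(all(diff(meds) > 0))
})

test_that("Jeffreys prior normalizations and scale invariance hold", {
  b <- bounds8()
  alpha <- median_log_blank(b)
  grid <- seq(0, log10(12), length.out = 2001)

  # constant F -> uniform prior of height 1/(alpha - log10 tau)
  const <- profile_from_values(grid, rep(4, 2001))
  jp <- jeffreys_prior(const, b)
  expect_equal(jp$density, rep(1 / alpha, length(jp$grid)), tolerance = 1e-9)
  expect_equal(jp$density, rep(2.619357, length(jp$grid)), tolerance = 1e-5)
  # the printed constant c = 2 * integral sqrt(F) makes the printed density
  # integrate to one half on the half-support
  expect_equal(plumecoding:::trapz(jp$grid, jp$density_printed), 0.5,
               tolerance = 1e-9)
  expect_equal(plumecoding:::trapz(jp$grid, jp$density), 1, tolerance = 1e-9)
  expect_equal(jp$c, 2 * 2 * alpha, tolerance = 1e-6)

  # F = k f^2 -> prior proportional to f restricted to the half-support
  f2 <- profile_from_values(grid, 7 * log_blank_density(grid, b)^2)
  jp2 <- jeffreys_prior(f2, b)
  f_restricted <- log_blank_density(jp2$grid, b)
  expect_equal(jp2$density,
               f_restricted / plumecoding:::trapz(jp2$grid, f_restricted),
               tolerance = 1e-6)

  # invariance under positive rescaling of F
  jp3 <- jeffreys_prior(profile_from_values(grid, 123 * f2$F), b)
  expect_equal(jp3$density, jp2$density, tolerance = 1e-12)

  expect_error(jeffreys_prior(profile_from_values(grid, rep(0, 2001)), b),
               "vanishes")
})

test_that("quantile comparison separates matching and mismatching priors", {
  b <- bounds8()
  grid <- seq(0, log10(12), length.out = 2001)
  matched <- jeffreys_prior(
    profile_from_values(grid, 3 * log_blank_density(grid, b)^2), b)
  qq <- qq_compare(matched, b)
  expect_lt(qq$max_abs_deviation, 1e-3)  # identical distributions

  uniform <- jeffreys_prior(profile_from_values(grid, rep(1, 2001)), b)
  qq_u <- qq_compare(uniform, b)
  expect_gt(qq_u$max_abs_deviation, 0.01)
  # the uniform prior puts more mass on long blanks than the decreasing
  # real density, so its upper quantiles overshoot
  tab <- qq_u$table
  expect_true(all(tab$predicted[tab$prob > 0.5] > tab$real[tab$prob > 0.5]))
})

test_that("mode correlation behaves at the extremes and rejects degeneracy", {
  expect_equal(mode_correlation(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(mode_correlation(c(3, 2, 1), c(1, 2, 3)), -1)
  expect_error(mode_correlation(c(1, 2), c(1, 2)), "at least 3")
  expect_error(mode_correlation(c(1, 1, 1), c(1, 2, 3)), "zero variance")
})

test_that("mode matching is preserved under monotone reparameterization", {
  # F proportional to f^2 keeps its mode aligned with the density mode
  # under any smooth monotone rescaling of the stimulus axis, because both
  # transform with powers of the same Jacobian.
  b <- bounds8()
  grid <- seq(0.01, log10(12), length.out = 4001)
  f <- log_blank_density(grid, b)
  F_val <- 2.5 * f^2
  g <- function(s) s^3 + 2 * s
  g_prime <- function(s) 3 * s^2 + 2
  F_new <- reparameterize(grid, F_val, g, g_prime, power = 2)
  f_new <- reparameterize(grid, f, g, g_prime, power = 1)
  mode_F <- F_new$grid[which.max(F_new$values)]
  mode_f <- f_new$grid[which.max(f_new$values)]
  expect_equal(mode_F, mode_f, tolerance = 1e-6)
})
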