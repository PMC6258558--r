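# Shared builders for tests. Everything is generated in code; no stored data.

bounds8 <- function() derive_timescales(plume_params(d = 8))

# A stimulus sequence built by hand: alternating blank/whiff with fixed
# durations, bypassing the sampler, for exact-contract tests.
fixed_sequence <- function(blank_dur, whiff_dur, n_pairs, d = 8) {
  dur <- rep(c(blank_dur, whiff_dur), n_pairs)
  onset <- cumsum(c(0, dur[-length(dur)]))
  total <- sum(dur)
  structure(list(
    events = data.frame(onset = onset, duration = dur,
                        kind = rep(c("blank", "whiff"), n_pairs),
                        truncated = FALSE, stringsAsFactors = FALSE),
    total_duration = total,
    params = plume_params(d = d),
    bounds = derive_timescales(plume_params(d = d)),
    seed = 0L, whiff_cap = Inf
  ), class = "stimulus_sequence")
}

# A recording built by hand from explicit spike times on a given sequence.
fixed_recording <- function(spikes, sequence, neuron_id = "fix1") {
  structure(list(spikes = sort(spikes), sequence = sequence,
                 distance = sequence$params$d, dose = 1e-2,
                 neuron_id = neuron_id, seed = 0L),
            class = "spike_train_recording")
}

# A Fisher profile built directly from grid values, bypassing estimation.
profile_from_values <- function(grid, F_val) {
  structure(list(grid = grid, F = F_val, mode = grid[which.max(F_val)],
                 support = range(grid),
                 reliable_support = range(grid) + c(0.2, -0.2) * diff(range(grid)),
                 normalized = FALSE),
            class = "fisher_profile")
}

# A duration_rate_fit built from closed-form gamma and sigma2.
fit_from_functions <- function(gamma, gamma_prime, sigma2, support,
                               grid_n = 201L) {
  grid <- seq(support[1], support[2], length.out = grid_n)
  structure(list(gamma = gamma, gamma_prime = gamma_prime, sigma2 = sigma2,
                 grid = grid, gamma_grid = gamma(grid),
                 gamma_prime_grid = gamma_prime(grid),
                 sigma2_grid = sigma2(grid), lambda = NA_real_, trace = 3,
                 support = support, n = 0L),
            class = "duration_rate_fit")
}

# Smooth monotone rescaling utility for the reparameterization invariance:
# under s -> g(s), a density transforms by 1/g'(s) and the Fisher
# information by 1/g'(s)^2, so mode coincidence of F and f^2 is preserved.
reparameterize <- function(grid, values, g, g_prime, power = 1) {
  list(grid = g(grid), values = values / g_prime(grid)^power)
}
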