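#' Parametric ORN encoding models
#'
#' An encoder specifies how a synthetic olfactory receptor neuron responds to
#' a whiff encounter: the expected spike count `mu(s)` in a fixed post-onset
#' response window as a function of `s`, the decadic log of the preceding
#' blank duration, together with a count-noise family, a response latency
#' `theta`, and a spontaneous rate `r0` active outside the response window.
#'
#' `make_saturating_encoder()` builds a sigmoidal duration-rate relationship
#' `mu(s) = window * (r0 + r_max / (1 + exp(-slope (s - s_half))))`, monotone
#' increasing in `s` — the typical shape of measured duration-rate curves.
#'
#' `make_jeffreys_matched_encoder()` builds a Poisson encoder whose Fisher
#' information is exactly proportional to the squared log-blank density of a
#' given plume distance: with `Flog` the log-scale blank CDF,
#' `sqrt(mu(s)) = sqrt(mu_min) + (c/2) * Flog(s)`, so that
#' `F(s) = mu'(s)^2 / mu(s) = c^2 * f_log10B(s)^2`. The induced Jeffreys
#' prior (proportional to `sqrt(F)`) then coincides with the blank-duration
#' distribution itself — the efficient-coding reference construction.
#'
#' @param r_max Maximum evoked firing rate (spikes/s).
#' @param s_half Half-saturation point (log10 s).
#' @param slope Sigmoid slope (per log10 unit).
#' @param r0 Spontaneous firing rate (spikes/s).
#' @param theta Response latency (s).
#' @param window Response-window length (s). Default 0.150.
#' @param noise Count-noise family, `"poisson"` or `"gaussian"`.
#' @param sigma2 For the Gaussian family, a function `s -> variance (counts^2)`.
#'
#' @return An object of class `encoder_spec` with fields `mu`, `mu_prime`
#'   (functions of `s`), `noise`, `sigma2`, `theta`, `r0`, `window`.
#' @examples
#' enc <- make_saturating_encoder(r_max = 100, s_half = 0.2, slope = 4, r0 = 5)
#' enc$mu(0.2) # 0.15 * 55 = 8.25
#' @export
make_saturating_encoder <- function(r_max, s_half, slope, r0 = 5,
                                    theta = 0.026, window = 0.150,
                                    noise = c("poisson", "gaussian"),
                                    sigma2 = NULL) {
  stopifnot_scalar_positive(r_max, "r_max")
  noise <- match.arg(noise)
  force(s_half); force(slope); force(r0); force(window)
  mu <- function(s) {
    sig <- 1 / (1 + exp(-slope * (s - s_half)))
    window * (r0 + r_max * sig)
  }
  mu_prime <- function(s) {
    sig <- 1 / (1 + exp(-slope * (s - s_half)))
    window * r_max * slope * sig * (1 - sig)
  }
  new_encoder(mu, mu_prime, noise, sigma2, theta, r0, window,
              label = "saturating")
}

#' @rdname make_saturating_encoder
#' @param bounds A [derive_timescales()] result the encoder is matched to.
#' @param mu_min Expected window count at the shortest blank (counts), > 0.
#' @param c_scale Fisher-information scale `c`; `F(s) = c^2 f_log10B(s)^2`.
#' @export
make_jeffreys_matched_encoder <- function(bounds, mu_min = 1, c_scale = 4,
                                          r0 = 5, theta = 0.026,
                                          window = 0.150) {
  stopifnot_scalar_positive(mu_min, "mu_min")
  if (c_scale < 0) stop("'c_scale' must be non-negative", call. = FALSE)
  force(bounds)
  root <- function(s) sqrt(mu_min) + (c_scale / 2) * log_blank_cdf(s, bounds)
  mu <- function(s) root(s)^2
  mu_prime <- function(s) c_scale * root(s) * log_blank_density(s, bounds)
  enc <- new_encoder(mu, mu_prime, "poisson", NULL, theta, r0, window,
                     label = "jeffreys_matched")
  enc$bounds <- bounds
  enc$c_scale <- c_scale
  enc
}

new_encoder <- function(mu, mu_prime, noise, sigma2, theta, r0, window,
                        label) {
  if (theta < 0) stop("'theta' must be non-negative", call. = FALSE)
  if (r0 < 0) stop("'r0' must be non-negative", call. = FALSE)
  stopifnot_scalar_positive(window, "window")
  if (noise == "gaussian" && !is.function(sigma2)) {
    stop("the gaussian noise family requires a 'sigma2' function",
         call. = FALSE)
  }
  structure(list(mu = mu, mu_prime = mu_prime, noise = noise,
                 sigma2 = sigma2, theta = theta, r0 = r0, window = window,
                 label = label),
            class = "encoder_spec")
}

#' @export
print.encoder_spec <- function(x, ...) {
  cat(sprintf(
    "ORN encoder (%s, %s noise): theta = %g s, r0 = %g sp/s, window = %g s\n",
    x$label, x$noise, x$theta, x$r0, x$window))
  invisible(x)
}

#' Closed-form Fisher information of a synthetic encoder
#'
#' For the Poisson family `F(s) = mu'(s)^2 / mu(s)`; for the Gaussian family
#' with known variance, `F(s) = mu'(s)^2 / sigma2(s)`. Serves as the exact
#' oracle the estimation pipeline is checked against.
#'
#' @param encoder An `encoder_spec`.
#' @param s Log10 blank durations.
#' @return Fisher information values (per log10 unit squared).
#' @export
analytic_fisher <- function(encoder, s) {
  mup <- encoder$mu_prime(s)
  if (encoder$noise == "poisson") {
    mu <- encoder$mu(s)
    out <- ifelse(mu > 0, mup^2 / mu, 0)
  } else if (encoder$noise == "gaussian") {
    out <- mup^2 / encoder$sigma2(s)
  } else {
    stop("unsupported noise family: ", encoder$noise, call. = FALSE)
  }
  out
}

#' Simulate a spike-train recording of one ORN
#'
#' Generates spike times for a neuron driven by a whiff/blank stimulus
#' sequence. During blanks (and whiff epochs outside the response window) the
#' neuron fires as a homogeneous Poisson process at the spontaneous rate
#' `r0`. For every whiff whose preceding blank is complete (not truncated at
#' the sequence boundary), a response count is drawn from the encoder's noise
#' family with mean `mu(s)` (`s` the log10 preceding-blank duration) and the
#' spikes are placed uniformly in the latency-corrected window
#' `[onset + theta, onset + theta + window]`. Whiffs without a complete
#' preceding blank receive spontaneous activity only.
#'
#' @param encoder An `encoder_spec`.
#' @param sequence A [generate_sequence()] result.
#' @param seed Integer seed.
#' @param neuron_id Identifier stored with the recording.
#' @param dose Dose label (ng) stored with the recording.
#' @param adaptation Optional list `list(gain0, tau)`: a multiplicative gain
#'   on `mu` decaying from `gain0` at time 0 to 1 with time constant `tau`
#'   (s), emulating the unstable early epoch of real recordings. Default off.
#'
#' @return An object of class `spike_train_recording`: sorted spike times,
#'   the stimulus sequence, and `(distance, dose, neuron_id)` metadata.
#' @export
simulate_recording <- function(encoder, sequence, seed, neuron_id = "orn1",
                               dose = NA_real_, adaptation = NULL) {
  if (!inherits(sequence, "stimulus_sequence")) {
    stop("'sequence' must be a stimulus_sequence", call. = FALSE)
  }
  theta <- encoder$theta
  win <- encoder$window
  if (theta + win > sequence$bounds$tau) {
    warning("response window (theta + window = ", theta + win,
            " s) exceeds the shortest whiff tau = ", sequence$bounds$tau,
            " s; response spikes may straddle whiff offsets", call. = FALSE)
  }
  ev <- sequence$events
  n_ev <- nrow(ev)
  gain <- function(t) {
    if (is.null(adaptation)) return(1)
    1 + (adaptation$gain0 - 1) * exp(-t / adaptation$tau)
  }

  # Response-eligible whiffs: preceding event is a complete blank.
  is_whiff <- ev$kind == "whiff"
  prev_ok <- c(FALSE, ev$kind[-n_ev] == "blank" & !ev$truncated[-n_ev])
  resp_idx <- which(is_whiff & prev_ok & !ev$truncated)

  sim <- function() {
    # spontaneous segments: all blanks; for responding whiffs the epochs
    # outside [theta, theta + window]; for other whiffs the whole event
    seg_start <- ev$onset[ev$kind == "blank"]
    seg_len <- ev$duration[ev$kind == "blank"]
    other_whiff <- setdiff(which(is_whiff), resp_idx)
    seg_start <- c(seg_start, ev$onset[other_whiff])
    seg_len <- c(seg_len, ev$duration[other_whiff])
    if (length(resp_idx)) {
      on <- ev$onset[resp_idx]; du <- ev$duration[resp_idx]
      seg_start <- c(seg_start, on, on + pmin(theta + win, du))
      seg_len <- c(seg_len, pmin(theta, du), pmax(du - theta - win, 0))
    }
    keep <- seg_len > 0
    seg_start <- seg_start[keep]; seg_len <- seg_len[keep]
    spikes <- numeric(0)
    if (encoder$r0 > 0 && length(seg_len)) {
      counts <- stats::rpois(length(seg_len), encoder$r0 * seg_len)
      spikes <- rep(seg_start, counts) +
        stats::runif(sum(counts)) * rep(seg_len, counts)
    }
    if (length(resp_idx)) {
      s_val <- log10(ev$duration[resp_idx - 1L])
      mu <- encoder$mu(s_val) * gain(ev$onset[resp_idx])
      r <- switch(encoder$noise,
        poisson = stats::rpois(length(mu), mu),
        gaussian = pmax(0L, round(stats::rnorm(
          length(mu), mu, sqrt(encoder$sigma2(s_val))))))
      starts <- ev$onset[resp_idx] + theta
      spikes <- c(spikes,
                  rep(starts, r) + stats::runif(sum(r)) * win)
    }
    sort(spikes[spikes >= 0 & spikes <= sequence$total_duration])
  }
  spikes <- withr::with_seed(seed, sim())
  structure(list(spikes = spikes, sequence = sequence,
                 distance = sequence$params$d, dose = dose,
                 neuron_id = neuron_id, seed = seed),
            class = "spike_train_recording")
}

#' @export
print.spike_train_recording <- function(x, ...) {
  cat(sprintf(
    "ORN recording '%s': %d spikes over %g s (d = %g m, dose = %s ng)\n",
    x$neuron_id, length(x$spikes), x$sequence$total_duration, x$distance,
    format(x$dose)))
  invisible(x)
}

#' Simulate a homogeneous population of ORN recordings
#'
#' Generates `n_neurons` independent recordings that share one encoding model
#' but each receive their own freshly generated stimulus sequence (each
#' sequence is presented to a single neuron only, as in single-sensillum
#' recordings). Per-recording seeds are derived deterministically from the
#' master seed.
#'
#' @inheritParams simulate_recording
#' @param params A [plume_params()] object for the shared virtual distance.
#' @param n_neurons Number of recordings.
#' @param duration_s Length of each recording (s).
#' @param tau,whiff_cap Passed to [generate_sequence()].
#' @return A list of `spike_train_recording` objects.
#' @export
simulate_population <- function(encoder, params, n_neurons, duration_s, seed,
                                dose = NA_real_, tau = NULL,
                                whiff_cap = NULL) {
  if (n_neurons < 1) stop("'n_neurons' must be at least 1", call. = FALSE)
  seeds <- derive_seeds(seed, 2L * n_neurons)
  lapply(seq_len(n_neurons), function(i) {
    sq <- generate_sequence(params, duration_s, seed = seeds[2L * i - 1L],
                            whiff_cap = whiff_cap, tau = tau)
    simulate_recording(encoder, sq, seed = seeds[2L * i],
                       neuron_id = sprintf("orn%03d", i), dose = dose)
  })
}

#' Expected number of whiff-blank pairs in a recording
#'
#' The mean blank and whiff durations are `sqrt(tau T_B)` and
#' `sqrt(tau T_W)`, so a time span `duration_s` contains on average
#' `duration_s / (sqrt(tau T_B) + sqrt(tau T_W))` blank-whiff pairs — a
#' planning helper for choosing recording lengths and population sizes.
#'
#' @param bounds A [derive_timescales()] result.
#' @param duration_s Time span (s).
#' @return Expected pair count.
#' @export
expected_whiff_pairs <- function(bounds, duration_s) {
  duration_s / (sqrt(bounds$tau * bounds$T_B) + sqrt(bounds$tau * bounds$T_W))
}
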