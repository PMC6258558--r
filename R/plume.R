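#' Physical parameters of a virtual turbulent pheromone plume
#'
#' Bundles the parameters that determine the whiff/blank duration statistics
#' experienced at a fixed point downwind of a pheromone source in a turbulent
#' flow: the downwind distance, the mean wind speed, the magnitude of the wind
#' fluctuations, the source size, and the intermittency (the fraction of time
#' the odorant is detectable).
#'
#' @param d Downwind distance from the source (m).
#' @param U Mean wind speed (m/s). Default 1.
#' @param dU Wind speed fluctuation (m/s). Default 0.1.
#' @param a Source size (m). Default 0.1.
#' @param chi Intermittency factor, strictly between 0 and 1. Default 0.4.
#'
#' @return An object of class `plume_params`.
#' @examples
#' plume_params(d = 8)
#' @export
plume_params <- function(d, U = 1, dU = 0.1, a = 0.1, chi = 0.4) {
  stopifnot_scalar_positive(d, "d")
  stopifnot_scalar_positive(U, "U")
  stopifnot_scalar_positive(dU, "dU")
  stopifnot_scalar_positive(a, "a")
  stopifnot_scalar_positive(chi, "chi")
  if (chi >= 1) stop("'chi' must be strictly less than 1", call. = FALSE)
  structure(list(d = d, U = U, dU = dU, a = a, chi = chi),
            class = "plume_params")
}

#' @export
print.plume_params <- function(x, ...) {
  cat(sprintf(
    "Plume parameters: d = %g m, U = %g m/s, dU = %g m/s, a = %g m, chi = %g\n",
    x$d, x$U, x$dU, x$a, x$chi))
  invisible(x)
}

#' Derive the plume timescale bounds
#'
#' Computes the shortest possible blank/whiff duration `tau`, the longest
#' whiff `T_W = d/U`, and the longest blank `T_B = T_W (1/chi - 1)`.
#' The default `tau = a^2 d / (d dU^2)` reduces to `a^2/dU^2` (the distance
#' cancels); an override is accepted because some plume scalings make the
#' shortest timescale grow with distance.
#'
#' @param params A [plume_params()] object.
#' @param tau Optional override of the shortest duration: either a positive
#'   number (s) or a function of the distance `d` returning one.
#'
#' @return An object of class `timescale_bounds` with fields `tau`, `T_W`,
#'   `T_B` (all in seconds) and the generating `params`.
#' @examples
#' derive_timescales(plume_params(d = 8))
#' @export
derive_timescales <- function(params, tau = NULL) {
  if (!inherits(params, "plume_params")) {
    stop("'params' must be a plume_params object", call. = FALSE)
  }
  if (is.null(tau)) {
    tau_val <- params$a^2 * params$d / (params$d * params$dU^2)
  } else if (is.function(tau)) {
    tau_val <- tau(params$d)
  } else {
    tau_val <- tau
  }
  stopifnot_scalar_positive(tau_val, "tau")
  T_W <- params$d / params$U
  T_B <- T_W * (1 / params$chi - 1)
  if (tau_val >= T_W || tau_val >= T_B) {
    stop("'tau' must be smaller than both T_W and T_B", call. = FALSE)
  }
  structure(list(tau = tau_val, T_W = T_W, T_B = T_B, params = params),
            class = "timescale_bounds")
}

#' @export
print.timescale_bounds <- function(x, ...) {
  cat(sprintf("Timescale bounds: tau = %g s, T_W = %g s, T_B = %g s\n",
              x$tau, x$T_W, x$T_B))
  invisible(x)
}

#' Truncated power-law duration distribution
#'
#' The distribution of whiff and blank durations in a turbulent plume:
#' density proportional to `x^(-3/2)` on a bounded support `[tau, T]`,
#' `f(x) = x^(-3/2) / (2 (1/sqrt(tau) - 1/sqrt(T)))`.
#'
#' @param tau Lower support bound (s).
#' @param T_max Upper support bound (s), `T_max > tau`.
#' @return An object of class `trunc_powerlaw`.
#' @seealso [blank_distribution()], [whiff_distribution()],
#'   [duration_quantile()], [sample_durations()]
#' @export
trunc_powerlaw <- function(tau, T_max) {
  stopifnot_scalar_positive(tau, "tau")
  stopifnot_scalar_positive(T_max, "T_max")
  if (T_max <= tau) stop("'T_max' must exceed 'tau'", call. = FALSE)
  structure(list(tau = tau, T_max = T_max,
                 norm = 2 * (1 / sqrt(tau) - 1 / sqrt(T_max))),
            class = "trunc_powerlaw")
}

#' @rdname trunc_powerlaw
#' @param bounds A [derive_timescales()] result.
#' @export
blank_distribution <- function(bounds) trunc_powerlaw(bounds$tau, bounds$T_B)

#' @rdname trunc_powerlaw
#' @export
whiff_distribution <- function(bounds) trunc_powerlaw(bounds$tau, bounds$T_W)

# density/cdf on the linear duration scale
dtpl <- function(x, dist) {
  out <- numeric(length(x))
  ok <- x >= dist$tau & x <= dist$T_max
  out[ok] <- x[ok]^(-3 / 2) / dist$norm
  out
}

ptpl <- function(x, dist) {
  x <- pmin(pmax(x, dist$tau), dist$T_max)
  (1 / sqrt(dist$tau) - 1 / sqrt(x)) / (dist$norm / 2)
}

#' Duration densities of the plume model
#'
#' `blank_density()` and `whiff_density()` evaluate the truncated power-law
#' probability densities of blank and whiff durations on the linear scale;
#' `log_blank_density()` evaluates the blank-duration density on the decadic
#' log scale, `f(s) = 10^(-s/2) ln(10) / (2 (1/sqrt(tau) - 1/sqrt(T_B)))`,
#' which is strictly decreasing so its mode sits at `log10(tau)`.
#' All return 0 outside the support.
#'
#' @param x Durations (s).
#' @param s Decadic log durations (log10 s).
#' @param bounds A [derive_timescales()] result.
#' @return Density values (1/s for the linear scale, per log10 unit for the
#'   log scale).
#' @examples
#' b <- derive_timescales(plume_params(d = 8))
#' blank_density(1, b)     # 0.7029137
#' log_blank_density(0, b) # 1.618519
#' @export
blank_density <- function(x, bounds) dtpl(x, blank_distribution(bounds))

#' @rdname blank_density
#' @export
whiff_density <- function(x, bounds) dtpl(x, whiff_distribution(bounds))

#' @rdname blank_density
#' @export
log_blank_density <- function(s, bounds) {
  dist <- blank_distribution(bounds)
  out <- numeric(length(s))
  ok <- s >= log10(dist$tau) & s <= log10(dist$T_max)
  out[ok] <- 10^(-s[ok] / 2) * log(10) / dist$norm
  out
}

#' @rdname blank_density
#' @export
log_blank_cdf <- function(s, bounds) ptpl(10^s, blank_distribution(bounds))

#' Quantile function of a truncated power-law duration distribution
#'
#' Inverts the CDF `(1/sqrt(tau) - 1/sqrt(x)) / (1/sqrt(tau) - 1/sqrt(T))`:
#' the `u`-quantile is `(1/sqrt(tau) - u (1/sqrt(tau) - 1/sqrt(T)))^(-2)`.
#'
#' @param u Probabilities in `[0, 1]`.
#' @param dist A [trunc_powerlaw()] object.
#' @return Durations (s), increasing in `u`; `u = 0` maps to `tau` and
#'   `u = 1` to `T_max`.
#' @examples
#' duration_quantile(0.5, trunc_powerlaw(1, 12)) # 2.408647
#' @export
duration_quantile <- function(u, dist) {
  if (any(!is.finite(u)) || any(u < 0) || any(u > 1)) {
    stop("'u' must lie in [0, 1]", call. = FALSE)
  }
  (1 / sqrt(dist$tau) - u * (dist$norm / 2))^(-2)
}

#' Sample durations by inverse-transform sampling
#'
#' @param n Number of draws.
#' @param dist A [trunc_powerlaw()] object.
#' @param seed Optional integer seed; when given, draws are reproducible and
#'   the caller's RNG state is untouched.
#' @return `n` i.i.d. durations (s). Their theoretical mean is
#'   `sqrt(tau * T_max)`.
#' @export
sample_durations <- function(n, dist, seed = NULL) {
  if (n < 1) stop("'n' must be at least 1", call. = FALSE)
  draw <- function() duration_quantile(stats::runif(n), dist)
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Generate a whiff/blank stimulus sequence
#'
#' Builds the virtual-plume stimulus: alternating blank and whiff events with
#' durations drawn independently from the truncated power-law distributions,
#' starting with a blank (every whiff response needs a measurable preceding
#' blank) and continuing until `total_duration` is covered; the final partial
#' event is kept but flagged as truncated. When a whiff cap is in force
#' (default 30 s at the two largest distances, 64 m and 128 m, where extremely
#' long whiffs would silence the neuron), whole sequences containing any whiff
#' longer than the cap are rejected and regenerated from fresh draws.
#'
#' @param params A [plume_params()] object.
#' @param total_duration Length of the sequence (s).
#' @param seed Integer seed; the sequence is fully reproducible given
#'   `(params, total_duration, seed)`.
#' @param whiff_cap Maximum admissible whiff duration (s); `NULL` selects the
#'   default rule (30 s for `d >= 64`, unlimited otherwise), `Inf` disables it.
#' @param tau Optional shortest-duration override, passed to
#'   [derive_timescales()].
#' @param max_attempts Limit on whole-sequence rejections before erroring.
#'
#' @return An object of class `stimulus_sequence`: a list with `events`
#'   (data.frame `onset`, `duration`, `kind`, `truncated`), `total_duration`,
#'   `params`, `bounds`, `seed`, `whiff_cap`.
#' @examples
#' seq8 <- generate_sequence(plume_params(d = 8), 200, seed = 1)
#' head(seq8$events)
#' @export
generate_sequence <- function(params, total_duration, seed,
                              whiff_cap = NULL, tau = NULL,
                              max_attempts = 1000L) {
  stopifnot_scalar_positive(total_duration, "total_duration")
  bounds <- derive_timescales(params, tau)
  if (is.null(whiff_cap)) {
    whiff_cap <- if (params$d >= 64) 30 else Inf
  }
  if (whiff_cap <= bounds$tau) {
    stop("whiff cap of ", whiff_cap, " s is below the shortest whiff tau = ",
         bounds$tau, " s", call. = FALSE)
  }
  fB <- blank_distribution(bounds)
  fW <- whiff_distribution(bounds)
  # expected pair length sqrt(tau T_B) + sqrt(tau T_W); draw with headroom
  pair_mean <- sqrt(bounds$tau * bounds$T_B) + sqrt(bounds$tau * bounds$T_W)

  build <- function() {
    for (attempt in seq_len(max_attempts)) {
      n_pairs <- ceiling(total_duration / pair_mean * 1.5) + 20L
      blanks <- numeric(0)
      whiffs <- numeric(0)
      repeat {
        u <- stats::runif(2L * n_pairs)
        blanks <- c(blanks, duration_quantile(u[seq(1L, length(u), 2L)], fB))
        whiffs <- c(whiffs, duration_quantile(u[seq(2L, length(u), 2L)], fW))
        if (sum(blanks) + sum(whiffs) >= total_duration) break
        n_pairs <- n_pairs  # draw another batch of the same size
      }
      dur <- as.vector(rbind(blanks, whiffs))
      kind <- rep(c("blank", "whiff"), length(blanks))
      ends <- cumsum(dur)
      last <- which(ends >= total_duration)[1L]
      dur <- dur[seq_len(last)]
      kind <- kind[seq_len(last)]
      onset <- c(0, cumsum(dur))[seq_len(last)]
      truncated <- c(rep(FALSE, last - 1L), TRUE)
      # truncate the final event at total_duration
      dur[last] <- total_duration - onset[last]
      if (dur[last] <= 0) { # boundary coincidence: drop empty final event
        dur <- dur[-last]; kind <- kind[-last]
        onset <- onset[-last]; truncated <- truncated[-last]
        truncated[length(truncated)] <- TRUE
      }
      if (is.finite(whiff_cap) &&
          any(dur[kind == "whiff"] > whiff_cap)) next
      return(list(events = data.frame(onset = onset, duration = dur,
                                      kind = kind, truncated = truncated,
                                      stringsAsFactors = FALSE),
                  attempts = attempt))
    }
    stop("failed to generate a sequence satisfying the whiff cap of ",
         whiff_cap, " s within ", max_attempts, " attempts", call. = FALSE)
  }
  res <- withr::with_seed(seed, build())
  structure(list(events = res$events, total_duration = total_duration,
                 params = params, bounds = bounds, seed = seed,
                 whiff_cap = whiff_cap, attempts = res$attempts),
            class = "stimulus_sequence")
}

#' @export
print.stimulus_sequence <- function(x, ...) {
  cat(sprintf(
    "Stimulus sequence: %d events over %g s (d = %g m, seed %d)\n",
    nrow(x$events), x$total_duration, x$params$d, x$seed))
  cat(sprintf("  whiff-time fraction: %.3f\n", realized_intermittency(x)))
  invisible(x)
}

#' Realized intermittency of a stimulus sequence
#'
#' Fraction of the total duration occupied by whiffs. For the truncated
#' power-law model its expectation is
#' `sqrt(T_W) / (sqrt(T_W) + sqrt(T_B))`, which differs from the nominal
#' intermittency factor `chi` entering the bounds.
#'
#' @param sequence A [generate_sequence()] result.
#' @return A number in `[0, 1]`.
#' @export
realized_intermittency <- function(sequence) {
  ev <- sequence$events
  sum(ev$duration[ev$kind == "whiff"]) / sequence$total_duration
}
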