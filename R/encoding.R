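#' Extract duration-response samples from a recording
#'
#' For every whiff whose onset lies in the analysis interval and whose
#' preceding blank is complete, counts the spikes in the latency-corrected
#' response window `[onset + theta, onset + theta + window)` and pairs the
#' count with `s = log10(preceding blank duration)`. Responses outside the
#' analysis interval are excluded: the duration-rate relationship is unstable
#' towards the beginning and end of real recordings, so only the adjusted
#' state is analysed.
#'
#' @param recording A `spike_train_recording`.
#' @param theta Response latency to correct for (s), typically a group-level
#'   [estimate_latency()] result.
#' @param window Response-window length (s). Default 0.150.
#' @param analysis_start,analysis_end Analysis interval (s of recording
#'   time). Defaults 100 and 500.
#' @return A data.frame with columns `s`, `r`, `onset`, `recording_id`.
#' @export
extract_responses <- function(recording, theta, window = 0.150,
                              analysis_start = 100, analysis_end = 500) {
  if (theta < 0) stop("'theta' must be non-negative", call. = FALSE)
  empty <- data.frame(s = numeric(0), r = integer(0), onset = numeric(0),
                      recording_id = character(0), stringsAsFactors = FALSE)
  if (analysis_start >= recording$sequence$total_duration) {
    warning("analysis interval lies outside the recording; no responses",
            call. = FALSE)
    return(empty)
  }
  ev <- recording$sequence$events
  n_ev <- nrow(ev)
  is_whiff <- ev$kind == "whiff"
  prev_ok <- c(FALSE, ev$kind[-n_ev] == "blank" & !ev$truncated[-n_ev])
  idx <- which(is_whiff & prev_ok & !ev$truncated &
                 ev$onset >= analysis_start & ev$onset <= analysis_end)
  if (!length(idx)) return(empty)
  onset <- ev$onset[idx]
  sp <- recording$spikes
  lo <- onset + theta
  hi <- lo + window
  r <- findInterval(hi - 1e-12, sp) - findInterval(lo - 1e-12, sp)
  data.frame(s = log10(ev$duration[idx - 1L]), r = as.integer(r),
             onset = onset,
             recording_id = rep(recording$neuron_id, length(idx)),
             stringsAsFactors = FALSE)
}

#' Pool duration-response samples across a recording group
#'
#' ORNs respond independently, so all recordings obtained at a given
#' distance and dose are pooled and analysed together. Samples are returned
#' sorted by `s` (as required by the segment-based variance estimator).
#'
#' @param recordings A list of `spike_train_recording` objects (one group).
#' @inheritParams extract_responses
#' @return A data.frame as in [extract_responses()], sorted by `s`.
#' @export
pool_samples <- function(recordings, theta, window = 0.150,
                         analysis_start = 100, analysis_end = 500) {
  if (inherits(recordings, "spike_train_recording")) {
    recordings <- list(recordings)
  }
  if (!length(recordings)) stop("empty recording group", call. = FALSE)
  out <- do.call(rbind, lapply(recordings, extract_responses, theta = theta,
                               window = window,
                               analysis_start = analysis_start,
                               analysis_end = analysis_end))
  out[order(out$s), , drop = FALSE]
}

#' Fit the duration-rate curve by a cubic smoothing spline
#'
#' Fits `gamma(s)`, the mean response as a function of the log blank
#' duration, as the piecewise cubic minimizing
#' `sum (r_i - gamma(s_i))^2 + lambda * integral gamma''(s)^2 ds`, with the
#' penalty chosen so that the trace of the smoother matrix (the effective
#' degrees of freedom) is close to `target_trace` (default 3, a gently
#' curved fit). The derivative `gamma'(s)` is taken analytically from the
#' fitted piecewise cubic.
#'
#' @param samples A data.frame with columns `s` and `r` (see
#'   [pool_samples()]).
#' @param target_trace Target smoother-matrix trace. Default 3.
#' @param trace_tol Acceptable deviation of the achieved trace. Default 0.1.
#' @return A list with functions `gamma` and `gamma_prime`, the penalty
#'   `lambda`, the achieved `trace`, `support` (range of `s`), and `n`.
#' @export
fit_duration_rate <- function(samples, target_trace = 3, trace_tol = 0.1) {
  s <- samples$s
  r <- samples$r
  if (length(s) < 10L) {
    stop("need at least 10 samples to fit the duration-rate curve",
         call. = FALSE)
  }
  if (length(unique(s)) < 4L) {
    stop("degenerate spread of blank durations: need >= 4 distinct s values",
         call. = FALSE)
  }
  fit <- stats::smooth.spline(s, r, df = target_trace, keep.data = FALSE)
  if (abs(fit$df - target_trace) > trace_tol) {
    # fall back to a manual bisection on spar: df is monotone decreasing in spar
    lo <- -1.5; hi <- 2.5
    for (i in 1:60) {
      mid <- (lo + hi) / 2
      f <- stats::smooth.spline(s, r, spar = mid, keep.data = FALSE)
      if (f$df > target_trace) lo <- mid else hi <- mid
      if (abs(f$df - target_trace) <= trace_tol / 2) break
    }
    fit <- f
  }
  if (abs(fit$df - target_trace) > target_trace) {
    stop("could not reach the target smoother trace", call. = FALSE)
  }
  list(
    gamma = function(x) stats::predict(fit, x)$y,
    gamma_prime = function(x) stats::predict(fit, x, deriv = 1)$y,
    lambda = fit$lambda,
    trace = fit$df,
    support = range(s),
    n = length(s)
  )
}

#' Robust segment variances of the responses
#'
#' Orders the responses by blank duration and slides a window of
#' `segment_size` consecutive responses (step 1). Each window yields a
#' robust variance estimate `(IQR(r) / 1.349)^2` located at the median `s`
#' of the window. Quartiles use linear interpolation between order
#' statistics (type-7 quantiles).
#'
#' @param samples A data.frame with columns `s`, `r`, sorted or not.
#' @param segment_size Responses per segment. Default 10.
#' @return A data.frame with columns `s_center`, `variance_raw`
#'   (counts^2), one row per window.
#' @export
robust_variance_points <- function(samples, segment_size = 10L) {
  ord <- order(samples$s)
  s <- samples$s[ord]
  r <- samples$r[ord]
  n <- length(s)
  if (n < segment_size) {
    stop("need at least 'segment_size' samples", call. = FALSE)
  }
  n_win <- n - segment_size + 1L
  s_center <- vapply(seq_len(n_win), function(i) {
    stats::median(s[i:(i + segment_size - 1L)])
  }, numeric(1))
  variance_raw <- vapply(seq_len(n_win), function(i) {
    (stats::IQR(r[i:(i + segment_size - 1L)]) / 1.349)^2
  }, numeric(1))
  data.frame(s_center = s_center, variance_raw = variance_raw)
}

#' Smooth the raw variance profile by tricube-weighted local lines
#'
#' Local linear regression of order 1: at each query point `s` a straight
#' line is fitted to the raw segment variances with tricube weights
#' `w(u) = (1 - |u|^3)^3` for `|u| <= 1`, `u = (s_center - s)/h`, where the
#' half-width `h` is `span_fraction * range(s_center) / 2` so the kernel's
#' full support spans `span_fraction` of the data range (default 90%). The
#' smoothed variance is floored at a small positive `eps` so downstream
#' Fisher-information ratios stay finite.
#'
#' @param points A [robust_variance_points()] result.
#' @param span_fraction Fraction of the data range spanned by the kernel.
#'   Default 0.9.
#' @param eps Positive floor on the returned variance (counts^2).
#' @return A vectorized function `sigma2(s)`.
#' @export
smooth_variance <- function(points, span_fraction = 0.9, eps = 1e-6) {
  sc <- points$s_center
  v <- points$variance_raw
  if (length(sc) < 2L) stop("need at least 2 variance points", call. = FALSE)
  h <- span_fraction * diff(range(sc)) / 2
  force(eps)
  function(s) {
    vapply(s, function(s0) {
      if (h <= 0) return(max(mean(v), eps))
      u <- (sc - s0) / h
      w <- ifelse(abs(u) <= 1, (1 - abs(u)^3)^3, 0)
      if (all(w == 0)) {
        stop("all tricube weights vanish at s = ", s0,
             " (query outside the spanned range)", call. = FALSE)
      }
      sw <- sum(w)
      xb <- sum(w * sc) / sw
      sxx <- sum(w * (sc - xb)^2)
      if (sxx < 1e-12) return(max(sum(w * v) / sw, eps))
      beta <- sum(w * (sc - xb) * v) / sxx
      alpha <- sum(w * v) / sw - beta * xb
      max(alpha + beta * s0, eps)
    }, numeric(1))
  }
}

#' Fit the full encoding model of a recording group
#'
#' Convenience wrapper running the whole within-group estimation:
#' smoothing-spline mean [fit_duration_rate()], robust segment variances
#' [robust_variance_points()], and tricube local-linear variance smoothing
#' [smooth_variance()], evaluated on a shared grid of equally spaced points
#' over the observed range of `s`.
#'
#' @param samples Pooled duration-response samples (see [pool_samples()]).
#' @inheritParams fit_duration_rate
#' @inheritParams robust_variance_points
#' @inheritParams smooth_variance
#' @param grid_n Number of evaluation-grid points. Default 201.
#' @return An object of class `duration_rate_fit`: functions `gamma`,
#'   `gamma_prime`, `sigma2`; vectors `grid`, `gamma_grid`,
#'   `gamma_prime_grid`, `sigma2_grid`; `lambda`, `trace`, `support`, `n`.
#' @export
fit_encoding_model <- function(samples, target_trace = 3, segment_size = 10L,
                               span_fraction = 0.9, grid_n = 201L,
                               eps = 1e-6) {
  mean_fit <- fit_duration_rate(samples, target_trace = target_trace)
  vpts <- robust_variance_points(samples, segment_size = segment_size)
  sigma2 <- smooth_variance(vpts, span_fraction = span_fraction, eps = eps)
  grid <- seq(mean_fit$support[1], mean_fit$support[2], length.out = grid_n)
  structure(list(
    gamma = mean_fit$gamma,
    gamma_prime = mean_fit$gamma_prime,
    sigma2 = sigma2,
    grid = grid,
    gamma_grid = mean_fit$gamma(grid),
    gamma_prime_grid = mean_fit$gamma_prime(grid),
    sigma2_grid = sigma2(grid),
    lambda = mean_fit$lambda,
    trace = mean_fit$trace,
    support = mean_fit$support,
    n = mean_fit$n,
    variance_points = vpts
  ), class = "duration_rate_fit")
}

#' @export
print.duration_rate_fit <- function(x, ...) {
  cat(sprintf(
    "Duration-rate fit: n = %d, trace = %.2f, support = [%.3f, %.3f] log10 s\n",
    x$n, x$trace, x$support[1], x$support[2]))
  invisible(x)
}
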