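#' Fisher-information coding-accuracy profile
#'
#' Approximates the Fisher information of the duration code as
#' `F(s) = gamma'(s)^2 / sigma2(s)`: the squared slope of the mean
#' duration-response curve over the response variance. Its reciprocal lower
#' bounds the mean square error of an ideal decoder of the log blank
#' duration, so `F` profiles decoding accuracy across stimulus timescales.
#' The mode is taken as the grid argmax (first grid point on ties). The
#' outer 20% of the sample support is flagged as unreliable: the spline
#' slope and the segment variances rest on few points there.
#'
#' @param fit A [fit_encoding_model()] result.
#' @return An object of class `fisher_profile`: `grid`, `F`, `mode`,
#'   `support`, `reliable_support` (central 60%), `normalized` flag.
#' @export
fisher_profile <- function(fit) {
  if (!inherits(fit, "duration_rate_fit")) {
    stop("'fit' must be a duration_rate_fit", call. = FALSE)
  }
  if (any(fit$sigma2_grid <= 0)) {
    stop("response variance must be positive everywhere", call. = FALSE)
  }
  F_val <- fit$gamma_prime_grid^2 / fit$sigma2_grid
  width <- diff(fit$support)
  structure(list(
    grid = fit$grid,
    F = F_val,
    mode = fit$grid[which.max(F_val)],
    support = fit$support,
    reliable_support = fit$support + c(0.2, -0.2) * width,
    normalized = FALSE
  ), class = "fisher_profile")
}

#' @export
print.fisher_profile <- function(x, ...) {
  cat(sprintf(
    "Fisher profile on [%.3f, %.3f] log10 s: mode at %.3f, max F = %.3g%s\n",
    x$support[1], x$support[2], x$mode, max(x$F),
    if (x$normalized) " (normalized)" else ""))
  invisible(x)
}

#' @export
plot.fisher_profile <- function(x, ...) {
  graphics::plot(x$grid, x$F, type = "l", xlab = "log10 blank duration (s)",
                 ylab = if (x$normalized) "F(s) / max F" else "F(s)", ...)
  graphics::abline(v = x$mode, lty = 2)
  invisible(x)
}

#' Normalize a Fisher profile to unit maximum
#'
#' Divides `F` by its maximum so profiles of different conditions can be
#' overlaid; the mode is unchanged and the operation is idempotent.
#'
#' @param profile A [fisher_profile()] result.
#' @return The profile with `max F = 1` and `normalized = TRUE`.
#' @export
normalize_profile <- function(profile) {
  m <- max(profile$F)
  if (m <= 0) stop("cannot normalize an all-zero profile", call. = FALSE)
  profile$F <- profile$F / m
  profile$normalized <- TRUE
  profile
}

#' Average Fisher information under a plume's blank statistics
#'
#' The average decoding accuracy `<F> = integral F(s) f_log10B(s) ds` over
#' the blank-duration distribution of a (possibly different) virtual
#' distance. The blank support must be covered by the profile support
#' (within a small edge tolerance: the observed sample range falls slightly
#' inside the theoretical support, and `F` is extended by its edge value
#' over the uncovered sliver). The integral is evaluated by the trapezoid
#' rule on a fine grid with `F` interpolated linearly from the profile grid.
#'
#' @param profile A [fisher_profile()] result.
#' @param bounds A [derive_timescales()] result supplying the blank
#'   distribution.
#' @param n_grid Integration-grid size. Default 2001.
#' @param edge_tol Largest tolerated gap (log10 units) between the blank
#'   support and the profile support at either edge. Default 0.05.
#' @return The scalar `<F>`; always between `min F` and `max F`.
#' @export
average_fisher <- function(profile, bounds, n_grid = 2001L,
                           edge_tol = 0.05) {
  lo <- log10(bounds$tau)
  hi <- log10(bounds$T_B)
  gap_lo <- profile$support[1] - lo
  gap_hi <- hi - profile$support[2]
  if (gap_lo > edge_tol || gap_hi > edge_tol) {
    stop(sprintf(
      paste0("Fisher profile support [%.3f, %.3f] does not cover the blank ",
             "support [%.3f, %.3f]; uncovered: %s"),
      profile$support[1], profile$support[2], lo, hi,
      paste(c(if (gap_lo > edge_tol) sprintf("[%.3f, %.3f]", lo, profile$support[1]),
              if (gap_hi > edge_tol) sprintf("[%.3f, %.3f]", profile$support[2], hi)),
            collapse = " and ")), call. = FALSE)
  }
  x <- seq(lo, hi, length.out = n_grid)
  F_x <- stats::approx(profile$grid, profile$F, xout = x, rule = 2)$y
  trapz(x, F_x * log_blank_density(x, bounds))
}

#' Average decoding accuracy under matched and mismatched plume statistics
#'
#' For each encoding model (one Fisher profile per matching virtual
#' distance) computes `<F>` under the blank statistics of the matching
#' distance and of every shorter distance. Longer distances cannot be
#' applied: their blank range exceeds the range over which the Fisher
#' information is defined, so the table is lower triangular. Each row is
#' flagged according to whether the matched (diagonal) entry is the row
#' maximum.
#'
#' @param profiles Named list of [fisher_profile()] objects, names = the
#'   matching distances (m).
#' @param bounds_list Named list of [derive_timescales()] objects for the
#'   same distances.
#' @param ... Passed to [average_fisher()].
#' @return An object of class `avg_fisher_table`: `table` (matrix, rows =
#'   matching distance, cols = applied distance, NA above the diagonal) and
#'   `matched_best` (logical per row).
#' @export
matched_vs_mismatched <- function(profiles, bounds_list, ...) {
  dists <- sort(as.numeric(names(profiles)))
  if (!setequal(names(profiles), names(bounds_list))) {
    stop("'profiles' and 'bounds_list' must cover the same distances",
         call. = FALSE)
  }
  k <- length(dists)
  tab <- matrix(NA_real_, k, k,
                dimnames = list(matching = dists, applied = dists))
  for (i in seq_len(k)) {
    for (j in seq_len(i)) {
      tab[i, j] <- average_fisher(profiles[[as.character(dists[i])]],
                                  bounds_list[[as.character(dists[j])]], ...)
    }
  }
  matched_best <- vapply(seq_len(k), function(i) {
    tab[i, i] >= max(tab[i, seq_len(i)])
  }, logical(1))
  structure(list(table = tab, matched_best = matched_best,
                 distances = dists),
            class = "avg_fisher_table")
}

#' @export
print.avg_fisher_table <- function(x, ...) {
  cat("Average Fisher information (rows: matching distance, cols: applied):\n")
  print(round(x$table, 4))
  cat("matched entry is row maximum:",
      paste(sprintf("%gm=%s", x$distances, x$matched_best), collapse = ", "),
      "\n")
  invisible(x)
}

#' Median of the log blank duration
#'
#' `alpha(0.5) = log10` of the blank-distribution median, obtained in closed
#' form from the quantile function; the upper end of the interval on which
#' the Jeffreys prior is evaluated.
#'
#' @param bounds A [derive_timescales()] result.
#' @return `alpha(0.5)` in log10 s.
#' @examples
#' median_log_blank(derive_timescales(plume_params(d = 8))) # 0.3817731
#' @export
median_log_blank <- function(bounds) {
  log10(duration_quantile(0.5, blank_distribution(bounds)))
}

#' Jeffreys prior induced by a Fisher profile
#'
#' The mutual-information-optimal stimulus distribution in the high
#' signal-to-noise (large-population) regime is the Jeffreys prior,
#' proportional to `sqrt(F(s))`. It is evaluated on
#' `[log10 tau, alpha(0.5)]`, the lower half of the blank support where the
#' Fisher information is most reliably estimated. Two normalizations are
#' returned: `density_printed = sqrt(F)/c` with `c = 2 * integral sqrt(F)`
#' over the interval (which integrates to 1/2 on this half-support), and
#' the unit-normalized `density` (integral 1), which is the default for
#' quantile comparisons. Both are invariant under positive rescaling of
#' `F`.
#'
#' @param profile A [fisher_profile()] result.
#' @param bounds A [derive_timescales()] result.
#' @param n_grid Evaluation-grid size. Default 1001.
#' @param edge_tol As in [average_fisher()].
#' @return An object of class `jeffreys_prior`: `grid`, `density`,
#'   `density_printed`, `c` (the `2 * integral sqrt(F)` constant),
#'   `support`.
#' @export
jeffreys_prior <- function(profile, bounds, n_grid = 1001L,
                           edge_tol = 0.05) {
  lo <- log10(bounds$tau)
  hi <- median_log_blank(bounds)
  if (profile$support[1] - lo > edge_tol || hi - profile$support[2] > edge_tol) {
    stop("Fisher profile does not cover [log10 tau, alpha(0.5)]",
         call. = FALSE)
  }
  x <- seq(lo, hi, length.out = n_grid)
  F_x <- pmax(stats::approx(profile$grid, profile$F, xout = x, rule = 2)$y, 0)
  sqrtF <- sqrt(F_x)
  total <- trapz(x, sqrtF)
  if (total <= 0) stop("Fisher information vanishes on the prior support",
                       call. = FALSE)
  structure(list(
    grid = x,
    density = sqrtF / total,
    density_printed = sqrtF / (2 * total),
    c = 2 * total,
    support = c(lo, hi)
  ), class = "jeffreys_prior")
}

#' @export
print.jeffreys_prior <- function(x, ...) {
  cat(sprintf(
    "Jeffreys prior on [%.3f, %.3f] log10 s (c = %.4g)\n",
    x$support[1], x$support[2], x$c))
  invisible(x)
}

#' Quantile-quantile comparison of the Jeffreys prior and the real blanks
#'
#' Compares the timescale distribution predicted by efficient coding (the
#' unit-normalized Jeffreys prior) with the real blank-duration distribution
#' conditioned on the same half-support `s <= alpha(0.5)`. Predicted
#' quantiles come from numeric inversion of the prior's CDF; real quantiles
#' are closed-form: the conditional `p`-quantile is the unconditional
#' `p/2`-quantile of the blank distribution.
#'
#' @param prior A [jeffreys_prior()] result.
#' @param bounds The matching [derive_timescales()] result.
#' @param probs Probability levels. Default `seq(0.01, 0.99, 0.01)`.
#' @return An object of class `qq_comparison`: data.frame `table` with
#'   columns `prob`, `predicted`, `real` (log10 s) and scalar
#'   `max_abs_deviation`.
#' @export
qq_compare <- function(prior, bounds, probs = seq(0.01, 0.99, by = 0.01)) {
  cdf <- cumtrapz(prior$grid, prior$density)
  cdf <- cdf / cdf[length(cdf)]
  # make the CDF strictly increasing for inversion
  keep <- c(TRUE, diff(cdf) > 0)
  predicted <- stats::approx(cdf[keep], prior$grid[keep], xout = probs,
                             rule = 2)$y
  real <- log10(duration_quantile(probs * 0.5, blank_distribution(bounds)))
  tab <- data.frame(prob = probs, predicted = predicted, real = real)
  structure(list(table = tab,
                 max_abs_deviation = max(abs(predicted - real))),
            class = "qq_comparison")
}

#' @export
print.qq_comparison <- function(x, ...) {
  cat(sprintf(
    "QQ comparison over %d levels: max |predicted - real| = %.4f log10 units\n",
    nrow(x$table), x$max_abs_deviation))
  invisible(x)
}

#' Correlation between coding-accuracy and stimulus-timescale modes
#'
#' Pearson correlation between the modes of the Fisher-information profiles
#' and the modes of the corresponding blank-duration distributions across
#' experimental conditions (both on the log10 scale). Values near 1 indicate
#' that peak coding accuracy tracks the most frequent blank duration.
#'
#' @param fi_modes Fisher-profile modes (log10 s), one per condition.
#' @param dist_modes Blank-distribution modes (log10 s), same length.
#' @return Pearson R.
#' @export
mode_correlation <- function(fi_modes, dist_modes) {
  if (length(fi_modes) != length(dist_modes) || length(fi_modes) < 3L) {
    stop("need at least 3 paired modes", call. = FALSE)
  }
  if (stats::sd(fi_modes) == 0 || stats::sd(dist_modes) == 0) {
    stop("correlation undefined: zero variance in the modes", call. = FALSE)
  }
  stats::cor(fi_modes, dist_modes)
}
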