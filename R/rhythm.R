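#' Estimate the circadian period of a sleep series by harmonic regression
#'
#' For each candidate period P on a dense grid, fits
#' `percent_asleep ~ intercept + beta_s * sin(2*pi*t/P) + beta_c * cos(2*pi*t/P)`
#' by least squares, and takes the period maximizing the harmonic power
#' (explained sum of squares, i.e. minimizing the residual sum of squares);
#' the fitted amplitude `sqrt(beta_s^2 + beta_c^2)` is reported at that
#' period, which is then polished by continuous optimization within one grid
#' step (see `refine`). Power is used rather than the raw coefficient amplitude because
#' with a finite record covering a non-integer number of cycles the
#' coefficient amplitude peaks slightly off the true period (spectral
#' leakage), while the power criterion recovers a pure noiseless cosine
#' exactly on the grid. Ties are broken toward the grid value nearest 24 h.
#' With 120 hourly samples a discrete Fourier transform has bins only at
#' 30, 24, 20, ... h — far too coarse for the 20-26 h free-running range —
#' so the regression grid is used instead.
#'
#' A series is flagged arrhythmic when the peak amplitude falls below
#' `k` times the residual standard deviation at the winning period
#' (default `k = 1`); a constant series yields the arrhythmic flag with an
#' `NA` period sentinel rather than an error.
#'
#' @param series A `sleep_series` object (see [to_sleep_series()]), or a
#'   numeric vector of percent-asleep values (then `hours` must be given).
#' @param grid Candidate periods in hours; default `seq(20, 28, by = 0.05)`.
#' @param hours Observation hours when `series` is a bare numeric vector.
#' @param k Arrhythmicity threshold multiplier on the residual SD.
#' @param refine After the grid search, polish the period by continuous
#'   one-dimensional optimization of the residual sum of squares within one
#'   grid step of the grid optimum (default TRUE); skipped when the grid
#'   optimum already fits exactly.
#' @return An object of class `rhythm_fit` with elements `tau`, `beta_sin`,
#'   `beta_cos`, `amplitude`, `phase` (acrophase in \[0, tau)), `mesor`,
#'   `arrhythmic`, `residual_sd`, `grid`, `grid_amplitude`, plus the data.
#' @examples
#' t <- 0:119
#' y <- 40 + 20 * cos(2 * pi * (t - 18) / 24)
#' fit <- estimate_period(y, hours = t)
#' fit$tau
#' @export
estimate_period <- function(series, grid = seq(20, 28, by = 0.05),
                            hours = NULL, k = 1, refine = TRUE) {
  if (inherits(series, "sleep_series")) {
    y <- series$percent_asleep
    t <- series$hours
    meta <- series[c("cage_id", "condition", "replicate_index")]
  } else {
    y <- as.numeric(series)
    t <- hours
    if (is.null(t)) stop("hours must be supplied for a numeric series")
    meta <- NULL
  }
  if (length(y) != length(t)) stop("series and hours lengths differ")
  span <- max(t) - min(t)
  if (span < 2 * max(grid))
    stop("series spans ", span, " h; need at least two full cycles (",
         2 * max(grid), " h) of the longest candidate period")

  fit <- list(grid = grid, data = list(hours = t, y = y), meta = meta, k = k)
  if (stats::sd(y) == 0) {
    fit <- c(fit, list(tau = NA_real_, beta_sin = 0, beta_cos = 0,
                       amplitude = 0, phase = NA_real_, mesor = y[1],
                       arrhythmic = TRUE, residual_sd = 0,
                       grid_amplitude = rep(0, length(grid))))
    class(fit) <- "rhythm_fit"
    return(fit)
  }

  amps <- rss <- numeric(length(grid))
  coefs <- matrix(NA_real_, length(grid), 3)
  for (i in seq_along(grid)) {
    w <- 2 * pi * t / grid[i]
    X <- cbind(1, sin(w), cos(w))
    f <- stats::lm.fit(X, y)
    coefs[i, ] <- f$coefficients
    amps[i] <- sqrt(f$coefficients[2]^2 + f$coefficients[3]^2)
    rss[i] <- sum(f$residuals^2)
  }
  top <- which(rss <= min(rss) + 1e-9 * (1 + min(rss)))
  best <- top[order(abs(grid[top] - 24), grid[top])][1]
  tau <- grid[best]
  b <- coefs[best, ]
  # local continuous refinement within one grid step (skipped when the grid
  # optimum already fits to machine precision, i.e. a noiseless harmonic)
  tss <- sum((y - mean(y))^2)
  if (refine && rss[best] > 1e-12 * tss) {
    step <- if (length(grid) > 1) grid[2] - grid[1] else 0.05
    lo <- max(min(grid), tau - step)
    hi <- min(max(grid), tau + step)
    rss_at <- function(P) {
      X <- cbind(1, sin(2 * pi * t / P), cos(2 * pi * t / P))
      sum(stats::lm.fit(X, y)$residuals^2)
    }
    opt <- stats::optimize(rss_at, c(lo, hi), tol = 1e-6)
    if (opt$objective < rss[best]) {
      tau <- opt$minimum
      X <- cbind(1, sin(2 * pi * t / tau), cos(2 * pi * t / tau))
      b <- stats::lm.fit(X, y)$coefficients
    }
  }
  resid <- y - cbind(1, sin(2 * pi * t / tau), cos(2 * pi * t / tau)) %*% b
  rsd <- sqrt(sum(resid^2) / max(1, length(y) - 3))
  phase <- (atan2(b[2], b[3]) / (2 * pi) * tau) %% tau

  amp <- sqrt(b[2]^2 + b[3]^2)
  fit <- c(fit, list(tau = tau, beta_sin = b[2], beta_cos = b[3],
                     amplitude = amp, phase = phase, mesor = b[1],
                     arrhythmic = amp < k * rsd, residual_sd = rsd,
                     grid_amplitude = amps))
  class(fit) <- "rhythm_fit"
  fit
}

#' @export
print.rhythm_fit <- function(x, ...) {
  cat("Harmonic regression period fit\n")
  if (!is.null(x$meta))
    cat(sprintf("  cage %s (%s, replicate %d)\n", x$meta$cage_id,
                x$meta$condition, x$meta$replicate_index))
  if (is.na(x$tau)) {
    cat("  arrhythmic (constant series); period undefined\n")
  } else {
    cat(sprintf("  tau = %.2f h, amplitude = %.2f%%, acrophase = %.2f h, mesor = %.2f%%\n",
                x$tau, x$amplitude, x$phase, x$mesor))
    if (x$arrhythmic)
      cat(sprintf("  flagged arrhythmic (amplitude < %g x residual SD %.2f)\n",
                  x$k, x$residual_sd))
  }
  invisible(x)
}

#' @export
summary.rhythm_fit <- function(object, ...) {
  print(object)
  if (!is.na(object$tau))
    cat(sprintf("  beta_sin = %.3f, beta_cos = %.3f, residual SD = %.3f, n = %d\n",
                object$beta_sin, object$beta_cos, object$residual_sd,
                length(object$data$y)))
  cat(sprintf("  grid searched: %.2f-%.2f h in %.3g h steps\n",
              min(object$grid), max(object$grid), object$grid[2] - object$grid[1]))
  invisible(object)
}

#' @export
coef.rhythm_fit <- function(object, ...) {
  c(mesor = object$mesor, beta_sin = object$beta_sin,
    beta_cos = object$beta_cos)
}

#' @export
fitted.rhythm_fit <- function(object, ...) {
  predict(object, hours = object$data$hours)
}

#' @export
predict.rhythm_fit <- function(object, hours = object$data$hours, ...) {
  if (is.na(object$tau)) return(rep(object$mesor, length(hours)))
  w <- 2 * pi * hours / object$tau
  object$mesor + object$beta_sin * sin(w) + object$beta_cos * cos(w)
}

#' @export
residuals.rhythm_fit <- function(object, ...) {
  object$data$y - fitted(object)
}

#' @export
plot.rhythm_fit <- function(x, ...) {
  plot(x$data$hours, x$data$y, xlab = "Hours from onset",
       ylab = "% asleep", pch = 16, col = "grey40", ...)
  if (!is.na(x$tau)) {
    h <- seq(min(x$data$hours), max(x$data$hours), by = 0.1)
    graphics::lines(h, predict(x, h), col = "firebrick", lwd = 2)
    graphics::mtext(sprintf("tau = %.2f h", x$tau), side = 3, line = 0.2)
  }
  invisible(x)
}

#' Paired difference curve against the LD control
#'
#' Computes `delta(t) = control(t) - cond(t)` hour by hour. Pairing is strictly
#' by replicate index (light:dark 1 minus constant-light 1, and so on); grids
#' and replicate indices must match.
#'
#' @param cond,control `sleep_series` objects on identical hour grids with
#'   equal `replicate_index`.
#' @return A data frame with columns `hour` and `delta` (percentage points),
#'   with attributes `condition`, `control`, `replicate_index`.
#' @export
pair_difference <- function(cond, control) {
  stopifnot(inherits(cond, "sleep_series"), inherits(control, "sleep_series"))
  if (!identical(cond$hours, control$hours))
    stop("hour grids differ between the paired series")
  if (cond$replicate_index != control$replicate_index)
    stop("pairing is by replicate index: got ", cond$replicate_index,
         " vs ", control$replicate_index)
  out <- data.frame(hour = cond$hours,
                    delta = control$percent_asleep - cond$percent_asleep)
  attr(out, "condition") <- cond$condition
  attr(out, "control") <- control$condition
  attr(out, "replicate_index") <- cond$replicate_index
  out
}

#' Trapezoidal area of a difference curve over a window
#'
#' @param curve Data frame with `hour` and `delta` columns (see
#'   [pair_difference()]).
#' @param window Half-open analysis window `[start, end)` in hours; default
#'   the fourth experimental day, `c(72, 96)`.
#' @param absolute If TRUE, integrate `|delta(t)|` instead of `delta(t)`.
#' @return Area in percent-asleep x hours.
#' @export
window_auc <- function(curve, window = c(72, 96), absolute = FALSE) {
  sel <- curve$hour >= window[1] & curve$hour < window[2]
  if (sum(sel) < 2) stop("window [", window[1], ", ", window[2],
                         ") contains fewer than 2 curve points")
  y <- curve$delta[sel]
  if (absolute) y <- abs(y)
  pracma::trapz(curve$hour[sel], y)
}

#' Midpoint-peak hour of a sleep series within a window
#'
#' Smooths the windowed curve with a centered 3-h moving average, thresholds
#' at half the smoothed range above the smoothed minimum, finds the longest
#' contiguous above-threshold run (ties broken by higher mean height, then
#' earlier time), and returns that run's temporal midpoint. A flat window
#' yields an `NA` sentinel.
#'
#' @param series A `sleep_series` object, or a data frame with `hour` and a
#'   value column named `percent_asleep` or `delta`.
#' @param window Half-open window `[start, end)`; default `c(72, 96)`.
#' @return Peak midpoint hour, or `NA_real_` when the window is flat.
#' @export
midpoint_peak <- function(series, window = c(72, 96)) {
  if (inherits(series, "sleep_series")) {
    h <- series$hours; y <- series$percent_asleep
  } else {
    h <- series$hour
    y <- if ("percent_asleep" %in% names(series)) series$percent_asleep else
      series$delta
  }
  sel <- h >= window[1] & h < window[2]
  if (!any(sel)) stop("window outside series support")
  h <- h[sel]; y <- y[sel]
  # centered 3-h moving average; shrinks to the available points at the edges
  sm <- vapply(seq_along(y), function(i) {
    mean(y[abs(h - h[i]) <= 1 + 1e-9])
  }, numeric(1))
  rng <- max(sm) - min(sm)
  if (rng == 0) return(NA_real_)
  thr <- min(sm) + rng / 2
  above <- sm >= thr - 1e-12
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- which(runs$values)
  lens <- runs$lengths[keep]
  best <- keep[lens == max(lens)]
  if (length(best) > 1) {
    heights <- vapply(best, function(j) mean(sm[starts[j]:ends[j]]), numeric(1))
    best <- best[order(-heights, starts[best])][1]
  }
  (h[starts[best]] + h[ends[best]]) / 2
}

#' Distance between midpoint peaks of a condition and its control
#'
#' `|midpoint_peak(cond) - midpoint_peak(control)|` over the same window; if
#' either peak is undefined (flat window), returns `NA` with a warning.
#'
#' @param cond,control `sleep_series` objects.
#' @param window Analysis window; default `c(72, 96)`.
#' @return Non-negative hours, or `NA_real_`.
#' @export
peak_distance <- function(cond, control, window = c(72, 96)) {
  p1 <- midpoint_peak(cond, window)
  p2 <- midpoint_peak(control, window)
  if (is.na(p1) || is.na(p2)) {
    warning("undefined peak in at least one series; distance is NA")
    return(NA_real_)
  }
  abs(p1 - p2)
}

#' Day-4 alignment of experimental conditions to the LD control
#'
#' For every LL and DD cage, pairs it by replicate index with the LD cage,
#' computes the paired difference curve, and summarizes signed and absolute
#' day-4 AUC plus midpoint-peak distance.
#'
#' @param series_list Named list of `sleep_series` (from [to_sleep_series()]).
#' @param window Day-4 window; default `c(72, 96)`.
#' @return Data frame with one row per LL/DD cage: `condition`,
#'   `replicate_index`, `auc_day4`, `abs_auc_day4`, `peak_distance`.
#' @export
align_to_control <- function(series_list, window = c(72, 96)) {
  conds <- vapply(series_list, `[[`, character(1), "condition")
  reps <- vapply(series_list, `[[`, integer(1), "replicate_index")
  rows <- list()
  for (i in which(conds %in% c("LL", "DD"))) {
    j <- which(conds == "LD" & reps == reps[i])
    if (length(j) != 1)
      stop("no unique LD control for ", series_list[[i]]$cage_id)
    curve <- pair_difference(series_list[[i]], series_list[[j]])
    rows[[length(rows) + 1]] <- data.frame(
      condition = conds[i],
      replicate_index = reps[i],
      auc_day4 = window_auc(curve, window, absolute = FALSE),
      abs_auc_day4 = window_auc(curve, window, absolute = TRUE),
      peak_distance = peak_distance(series_list[[i]], series_list[[j]], window),
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, rows)
  res[order(res$condition, res$replicate_index), , drop = FALSE]
}
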