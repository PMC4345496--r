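# Peak detection and limit-cycle measurement.
#
# The period of a free-running oscillator is measured from the return
# map of a phase-anchoring event: after a settle horizon, upward
# crossings of a marker variable through its trailing-window mean are
# located by interpolation and the period is the mean of the last few
# return intervals.  Entrained variants have their period locked to the
# forcing; only convergence to the entrained cycle is checked.

#' Detect peaks of one variable of a trajectory
#'
#' Grid-local maxima refined by parabolic interpolation through the three
#' bracketing samples.  Peaks whose prominence (height above the higher
#' of the two flanking minima between neighbouring peaks or the series
#' ends) is below `prominence_frac * range(signal)` are discarded.
#'
#' @param traj A `cv_trajectory` from [integrate_variant()].
#' @param j Variable index (column of the state matrix).
#' @param config A [cv_config()] list (`prominence_frac`).
#' @return A tibble of class `cv_peaks` with columns `time`, `level`
#'   (both parabola-refined) and `grid_index`, ordered by time.
#' @export
#' @examples
#' tr <- structure(list(times = seq(0, 20, 0.01),
#'                      states = cbind(x = sin(seq(0, 20, 0.01))),
#'                      variant_id = "toy", params = NULL),
#'                 class = "cv_trajectory")
#' detect_peaks(tr, 1)$time  # ~ pi/2 + 2*pi*(0:2)
detect_peaks <- function(traj, j, config = cv_config()) {
  y <- traj$states[, j]
  t <- traj$times
  if (length(y) < 3) abort_input("Need at least 3 samples to detect peaks.")
  rng <- diff(range(y))
  if (rng == 0) {
    out <- tibble::tibble(time = double(), level = double(), grid_index = integer())
    class(out) <- c("cv_peaks", class(out))
    return(out)
  }
  d <- diff(y)
  # interior strict local maxima; plateau tops (zero diff) are skipped
  idx <- which(d[-length(d)] > 0 & d[-1] < 0) + 1
  if (length(idx) == 0) {
    out <- tibble::tibble(time = double(), level = double(), grid_index = integer())
    class(out) <- c("cv_peaks", class(out))
    return(out)
  }
  floor_h <- config$prominence_frac * rng
  keep <- logical(length(idx))
  for (p in seq_along(idx)) {
    lo <- if (p == 1) 1 else idx[p - 1]
    hi <- if (p == length(idx)) length(y) else idx[p + 1]
    left_min <- min(y[lo:idx[p]])
    right_min <- min(y[idx[p]:hi])
    prom <- y[idx[p]] - max(left_min, right_min)
    keep[p] <- prom >= floor_h
  }
  idx <- idx[keep]
  refined <- vapply(idx, function(i) {
    refine_parabola(t[i - 1], t[i], t[i + 1], y[i - 1], y[i], y[i + 1])
  }, numeric(3))
  out <- tibble::tibble(
    time = refined[1, ], level = refined[2, ], grid_index = idx
  )
  class(out) <- c("cv_peaks", class(out))
  out
}

# Vertex (t*, y*, curvature) of the parabola through three points.
refine_parabola <- function(t1, t2, t3, y1, y2, y3) {
  # quadratic in u = t - t2
  u1 <- t1 - t2
  u3 <- t3 - t2
  denom <- u1 * u3 * (u1 - u3)
  a <- (u3 * (y1 - y2) - u1 * (y3 - y2)) / denom
  b <- (u1^2 * (y3 - y2) - u3^2 * (y1 - y2)) / denom
  if (a >= 0) {
    # no concave vertex: fall back to the grid sample
    return(c(t2, y2, 2 * a))
  }
  ustar <- -b / (2 * a)
  c(t2 + ustar, y2 + b * ustar + a * ustar^2, 2 * a)
}

#' Average peak-to-peak period
#'
#' Mean spacing between consecutive peaks from the `first_index`-th peak
#' (1-based) to the last — the estimator used for transient oscillations
#' whose first cycles are distorted by the initial response.
#'
#' @param peaks A `cv_peaks` tibble from [detect_peaks()].
#' @param first_index First peak included (default 3).
#' @return The mean consecutive spacing (model time units).
#' @export
#' @examples
#' pk <- tibble::tibble(time = seq(0, 50, 10), level = 1, grid_index = 1:6)
#' average_peak_period(pk)   # 10
average_peak_period <- function(peaks, first_index = 3) {
  if (!is.data.frame(peaks) || !"time" %in% names(peaks)) {
    abort_input("`peaks` must be a peak list with a `time` column.")
  }
  n <- nrow(peaks)
  if (first_index < 1) abort_input("`first_index` must be >= 1.")
  if (n < first_index + 1) {
    abort_input(sprintf(
      "Need at least %d peaks (got %d) for first_index = %d.",
      first_index + 1, n, first_index
    ))
  }
  tt <- peaks$time[first_index:n]
  mean(diff(tt))
}

#' Find the attracting periodic orbit of a periodic variant
#'
#' Free-running variants: after a crude integration (used both to settle
#' onto the attractor and to estimate the period from peak spacings), the
#' orbit is sampled densely and anchored on upward crossings of the
#' marker variable through its window mean; the period is the mean of
#' the trailing return intervals, which must agree to within
#' `return_rel_tol`.  Entrained variants (repeating input schedule): the
#' period is locked to the forcing period and only convergence to the
#' entrained cycle is checked.  Both paths verify the closure error
#' `||x(t0 + tau) - x(t0)||` relative to the state scale.
#'
#' @param variant A periodic [ge_variant()].
#' @param params Named parameter vector (defaults to reference values).
#' @param config A [cv_config()] list.
#' @param marker Index of the anchoring variable (default 1).
#' @return An object of class `cv_orbit`: list with `period`,
#'   `entrained`, `anchor_state` (state at the anchoring event),
#'   `anchor_time`, `one_period` (a `cv_trajectory` over `[0, tau]`
#'   starting at the anchor), `closure_error`, `return_intervals`,
#'   `phase_event` (description), `variant_id`.
#' @export
find_periodic_orbit <- function(variant, params = NULL, config = cv_config(),
                                marker = 1) {
  if (!inherits(variant, "cv_variant")) abort_input("`variant` must be a cv_variant.")
  if (variant$solution_kind != "periodic") {
    abort_input("`find_periodic_orbit` requires a periodic variant.")
  }
  nominal <- variant$model$nominal_period
  if (is.null(nominal)) abort_input("Model has no nominal_period; cannot size settle horizon.")

  if (variant$entrained) {
    return(entrained_orbit(variant, params, config, marker))
  }

  # --- stage 1: settle + crude period estimate -------------------------
  t_settle <- config$settle_periods * nominal
  crude_grid <- seq(0, t_settle + 10 * nominal, by = nominal / 50)
  traj <- integrate_variant(variant, params, crude_grid, config = config)
  tail_idx <- which(traj$times >= t_settle)
  y_tail <- traj$states[tail_idx, marker]
  if (diff(range(y_tail)) < config$amplitude_floor) {
    abort_no_oscillation(paste0(
      "Variant '", variant$id, "': oscillation amplitude ",
      format(diff(range(y_tail))), " below floor ", format(config$amplitude_floor), "."
    ))
  }
  tail_traj <- structure(
    list(times = traj$times[tail_idx], states = traj$states[tail_idx, , drop = FALSE],
         variant_id = variant$id, params = traj$params),
    class = "cv_trajectory"
  )
  pk <- detect_peaks(tail_traj, marker, config)
  if (nrow(pk) < 4) {
    abort_no_oscillation(paste0("Variant '", variant$id, "': fewer than 4 peaks after settling."))
  }
  crude <- mean(diff(utils::tail(pk$time, min(10, nrow(pk)))))

  # --- stage 2: dense measurement --------------------------------------
  n_meas <- config$n_return_intervals + 3
  x_start <- traj$states[nrow(traj$states), ]
  dt <- crude / config$steps_per_period
  fine_grid <- seq(0, n_meas * crude, by = dt)
  fine <- integrate_variant(variant, params, fine_grid, x0 = x_start, config = config)
  y <- fine$states[, marker]
  mu <- mean(y)
  cross <- upward_crossings(fine$times, y, mu)
  if (length(cross) < config$n_return_intervals + 1) {
    abort_not_converged(paste0("Variant '", variant$id, "': too few anchor returns."))
  }
  intervals <- diff(cross)
  last <- utils::tail(intervals, config$n_return_intervals)
  tau <- mean(last)
  if (max(abs(last - tau)) / tau > config$return_rel_tol) {
    abort_not_converged(paste0(
      "Variant '", variant$id, "': return intervals not converged (rel spread ",
      format(max(abs(last - tau)) / tau), ")."
    ))
  }

  # --- anchor state and closure ----------------------------------------
  t_anchor <- cross[length(cross) - 1]
  x_anchor <- interp_state(fine, t_anchor)
  per_grid <- seq(0, tau, length.out = config$steps_per_period + 1)
  one <- integrate_variant(variant, params, per_grid, x0 = x_anchor, config = config)
  scale <- max(abs(one$states))
  closure <- sqrt(sum((one$states[nrow(one$states), ] - x_anchor)^2)) / scale
  if (closure > config$closure_tol) {
    abort_not_converged(paste0(
      "Variant '", variant$id, "': closure error ", format(closure),
      " above tolerance ", format(config$closure_tol), "."
    ))
  }
  structure(
    list(
      period = tau, entrained = FALSE,
      anchor_state = x_anchor, anchor_time = t_anchor,
      one_period = one, closure_error = closure,
      return_intervals = intervals,
      phase_event = paste0("upward crossing of variable ", marker, " through cycle mean"),
      variant_id = variant$id
    ),
    class = "cv_orbit"
  )
}

# Entrained cycle: period = forcing period; anchor at schedule phase 0.
# Convergence to the entrained cycle is linear with a Floquet factor that
# can be close to 1, so the settle horizon is three times the free-running
# one; the settle grid is sparse (the integrator's internal steps are
# adaptive regardless).
entrained_orbit <- function(variant, params, config, marker) {
  P <- variant$schedule$period
  n_settle <- 3 * config$settle_periods
  grid <- seq(0, n_settle * P, by = P / 4)
  traj <- integrate_variant(variant, params, grid, config = config)
  x_anchor <- traj$states[nrow(traj$states), ]
  per_grid <- seq(0, P, length.out = config$steps_per_period + 1)
  # integrate from external time n_settle*P so the schedule phase is kept
  one <- integrate_variant(variant, params, per_grid + n_settle * P,
                           x0 = x_anchor, config = config)
  one$times <- one$times - n_settle * P
  y <- one$states[, marker]
  if (diff(range(y)) < config$amplitude_floor) {
    abort_no_oscillation(paste0("Variant '", variant$id, "': entrained amplitude below floor."))
  }
  scale <- max(abs(one$states))
  closure <- sqrt(sum((one$states[nrow(one$states), ] - x_anchor)^2)) / scale
  if (closure > config$closure_tol) {
    abort_not_converged(paste0(
      "Variant '", variant$id, "': entrained cycle not converged (closure ",
      format(closure), ")."
    ))
  }
  structure(
    list(
      period = P, entrained = TRUE,
      anchor_state = x_anchor, anchor_time = 0,
      one_period = one, closure_error = closure,
      return_intervals = numeric(0),
      phase_event = "external forcing phase 0",
      variant_id = variant$id
    ),
    class = "cv_orbit"
  )
}

#' @export
print.cv_orbit <- function(x, ...) {
  cat("<cv_orbit> variant '", x$variant_id, "', period = ", format(x$period),
      if (x$entrained) " (entrained)" else "", "\n", sep = "")
  cat("  closure error = ", format(x$closure_error), "\n", sep = "")
  invisible(x)
}

# Times of upward crossings of y through level, linearly interpolated.
upward_crossings <- function(t, y, level) {
  z <- y - level
  i <- which(z[-length(z)] < 0 & z[-1] >= 0)
  t[i] + (t[i + 1] - t[i]) * (-z[i]) / (z[i + 1] - z[i])
}

# Linear interpolation of the full state at time tt.
interp_state <- function(traj, tt) {
  i <- findInterval(tt, traj$times)
  i <- max(1, min(i, length(traj$times) - 1))
  w <- (tt - traj$times[i]) / (traj$times[i + 1] - traj$times[i])
  (1 - w) * traj$states[i, ] + w * traj$states[i + 1, ]
}
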