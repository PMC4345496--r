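# Feature evaluation and finite-difference sensitivities in logged
# parameters.
#
# All feature gradients use central finite differences with a
# multiplicative step exp(+-h) on each perturbable parameter (h =
# config$fd_step), which is exactly a central difference in the logged
# parameter.  For free-running periodic variants every perturbed orbit
# is re-anchored to its own phase event before features are read off
# (fixed-phase convention); entrained and transient variants are sampled
# at fixed external time.

# ---------------------------------------------------------------------
# Feature requests: a request is list(name, kind, j, t, delta, n1, n2).
feature_request <- function(name, kind, j = NA, t = NA, delta = NA,
                            n1 = NA, n2 = NA) {
  list(name = name, kind = kind, j = j, t = t, delta = delta, n1 = n1, n2 = n2)
}

# Evaluate a set of features of a variant's solution of interest at one
# parameter vector.  Returns a named numeric vector.
variant_features <- function(variant, params, requests, config = cv_config()) {
  kinds <- vapply(requests, `[[`, character(1), "kind")
  ok_kinds <- c("level", "period", "peak_time", "amplitude", "fall_ratio",
                "peak_level", "peak_ratio")
  bad <- setdiff(kinds, ok_kinds)
  if (length(bad) > 0) abort_input(paste0("Unknown feature kind(s): ", paste(bad, collapse = ", ")))

  if (variant$solution_kind == "transient") {
    features_transient(variant, params, requests, config)
  } else if (variant$entrained) {
    features_entrained(variant, params, requests, config)
  } else {
    features_freerun(variant, params, requests, config)
  }
}

# Transient output grid: resolution per nominal period, capped.
transient_grid <- function(variant, config) {
  nominal <- variant$model$nominal_period
  if (is.null(nominal)) nominal <- variant$horizon
  n_steps <- min(20000, max(2000, round(
    variant$horizon / nominal * config$transient_steps_per_period
  )))
  seq(0, variant$horizon, length.out = n_steps + 1)
}

features_transient <- function(variant, params, requests, config) {
  horizon <- variant$horizon
  grid <- transient_grid(variant, config)
  lvl_times <- unlist(lapply(requests, function(r) if (r$kind == "level") r$t else NULL))
  if (length(lvl_times) > 0) {
    if (any(lvl_times < 0 | lvl_times > horizon)) {
      abort_input("Level times must lie within [0, horizon].")
    }
    grid <- sort(unique(c(grid, lvl_times)))
  }
  traj <- integrate_variant(variant, params, grid, config = config)
  peak_cache <- list()
  get_peaks <- function(j) {
    key <- as.character(j)
    if (is.null(peak_cache[[key]])) peak_cache[[key]] <<- detect_peaks(traj, j, config)
    peak_cache[[key]]
  }
  sapply_named(requests, function(r) {
    switch(r$kind,
      level = {
        i <- match_time(traj$times, r$t)
        traj$states[i, r$j]
      },
      amplitude = diff(range(traj$states[, r$j])),
      period = average_peak_period(get_peaks(r$j), first_index = req_or(r$n1, 3)),
      peak_time = peak_feature(traj, get_peaks(r$j), r$j, req_or(r$n1, 1), config)["time"],
      peak_level = peak_feature(traj, get_peaks(r$j), r$j, req_or(r$n1, 1), config)["level"],
      peak_ratio = {
        pk <- get_peaks(r$j)
        l1 <- peak_feature(traj, pk, r$j, r$n1, config)["level"]
        l2 <- peak_feature(traj, pk, r$j, r$n2, config)["level"]
        unname(l2 / l1)
      },
      fall_ratio = fall_ratio_from(traj$times, traj$states[, r$j],
                                   get_peaks(r$j), req_or(r$n1, 1),
                                   req_or(r$delta, config$fall_ratio_offset),
                                   config, wrap = NA, traj = traj, j = r$j)
    )
  })
}

features_entrained <- function(variant, params, requests, config) {
  orbit <- find_periodic_orbit(variant, params, config)
  one <- orbit$one_period
  P <- orbit$period
  sapply_named(requests, function(r) {
    switch(r$kind,
      period = P, # forcing-locked: constant in the parameters
      level = {
        if (r$t < 0 || r$t > P) abort_input("Entrained level time must lie in [0, period].")
        spline_at(one$times, one$states[, r$j], r$t)
      },
      amplitude = diff(range(one$states[, r$j])),
      peak_time = peak_feature(one, detect_peaks(one, r$j, config), r$j,
                               req_or(r$n1, 1), config)["time"],
      peak_level = peak_feature(one, detect_peaks(one, r$j, config), r$j,
                                req_or(r$n1, 1), config)["level"],
      peak_ratio = {
        pk <- detect_peaks(one, r$j, config)
        unname(peak_feature(one, pk, r$j, r$n2, config)["level"] /
               peak_feature(one, pk, r$j, r$n1, config)["level"])
      },
      fall_ratio = fall_ratio_from(one$times, one$states[, r$j],
                                   detect_peaks(one, r$j, config), req_or(r$n1, 1),
                                   req_or(r$delta, config$fall_ratio_offset),
                                   config, wrap = P, traj = one, j = r$j)
    )
  })
}

features_freerun <- function(variant, params, requests, config) {
  orbit <- find_periodic_orbit(variant, params, config)
  one <- orbit$one_period
  tau <- orbit$period
  sapply_named(requests, function(r) {
    switch(r$kind,
      period = tau,
      level = {
        # fixed-phase convention: t is a phase fraction of the cycle
        if (r$t < 0 || r$t >= 1) {
          abort_input("Free-running level times are phase fractions in [0, 1).")
        }
        spline_at(one$times, one$states[, r$j], r$t * tau)
      },
      amplitude = diff(range(one$states[, r$j])),
      peak_time = peak_feature(one, detect_peaks(one, r$j, config), r$j,
                               req_or(r$n1, 1), config)["time"],
      peak_level = peak_feature(one, detect_peaks(one, r$j, config), r$j,
                                req_or(r$n1, 1), config)["level"],
      peak_ratio = {
        pk <- detect_peaks(one, r$j, config)
        unname(peak_feature(one, pk, r$j, r$n2, config)["level"] /
               peak_feature(one, pk, r$j, r$n1, config)["level"])
      },
      fall_ratio = fall_ratio_from(one$times, one$states[, r$j],
                                   detect_peaks(one, r$j, config), req_or(r$n1, 1),
                                   req_or(r$delta, config$fall_ratio_offset),
                                   config, wrap = tau, traj = one, j = r$j)
    )
  })
}

# --- small helpers ----------------------------------------------------

sapply_named <- function(requests, f) {
  out <- vapply(requests, function(r) as.double(f(r))[1], numeric(1))
  names(out) <- vapply(requests, `[[`, character(1), "name")
  out
}

req_or <- function(x, default) if (is.null(x) || is.na(x)) default else x

match_time <- function(times, t, tol = 1e-9) {
  i <- which(abs(times - t) <= tol * max(1, abs(t)))
  if (length(i) == 0) {
    abort_input(paste0("Time ", format(t), " is not on the trajectory grid; no silent interpolation."))
  }
  i[1]
}

spline_at <- function(times, y, t) {
  stats::splinefun(times, y, method = "fmm")(t)
}

# n-th refined peak of variable j; checks existence and curvature.
# On top of the grid-level parabolic bracketing of detect_peaks(), the
# peak is re-refined on a local spline window: sharp peaks otherwise
# carry a curvature-dependent O(dt^2) level bias that leaks into feature
# gradients.
peak_feature <- function(traj, peaks, j, n, config) {
  if (is.null(n) || is.na(n)) abort_input("Peak index is required.")
  if (nrow(peaks) < n) {
    abort_degenerate_peak(sprintf(
      "Variable %s has %d detected peak(s); peak %d requested.", j, nrow(peaks), n
    ))
  }
  i <- peaks$grid_index[n]
  y <- traj$states[, j]
  tt <- traj$times
  curv <- refine_parabola(tt[i - 1], tt[i], tt[i + 1], y[i - 1], y[i], y[i + 1])[3]
  dt <- tt[i + 1] - tt[i]
  rng <- diff(range(y))
  if (abs(curv) < config$curvature_floor * rng / dt^2 * 1e-4) {
    abort_degenerate_peak(sprintf("Peak %d of variable %s is degenerate (flat top).", n, j))
  }
  lo <- max(1, i - 4)
  hi <- min(length(tt), i + 4)
  sf <- stats::splinefun(tt[lo:hi], y[lo:hi], method = "fmm")
  opt <- stats::optimize(sf, c(tt[max(lo, i - 1)], tt[min(hi, i + 1)]),
                         maximum = TRUE, tol = 1e-10)
  c(time = opt$maximum, level = opt$objective)
}

# Fall ratio R = g(phi + delta) / g(phi) (or phi - delta for the
# "before" side).  `wrap` = period for cyclic signals, NA for transients.
fall_ratio_from <- function(times, y, peaks, n, delta, config, wrap = NA,
                            traj = NULL, j = NULL) {
  if (nrow(peaks) < n) {
    abort_degenerate_peak(sprintf("Fall ratio needs peak %d; only %d detected.", n, nrow(peaks)))
  }
  if (!is.null(traj)) {
    pf <- peak_feature(traj, peaks, j, n, config)
    phi <- unname(pf["time"])
    lv <- unname(pf["level"])
  } else {
    phi <- peaks$time[n]
    lv <- peaks$level[n]
  }
  if (abs(lv) < 1e-12) {
    abort_input("Peak level below positivity floor; fall ratio undefined.")
  }
  if (delta == 0) return(1)
  t2 <- if (config$fall_ratio_side == "after") phi + delta else phi - delta
  if (!is.na(wrap)) {
    t2 <- t2 %% wrap
  } else if (t2 < min(times) || t2 > max(times)) {
    abort_input("Fall-ratio offset falls outside the trajectory horizon.")
  }
  spline_at(times, y, t2) / lv
}

# ---------------------------------------------------------------------
# Gradients of a set of features in logged parameters.
#
# Returns list(values = named vector at base params,
#              gradients = n_features x s matrix over the full axis,
#              mask = perturbable mask used).
feature_gradients <- function(variant, params = NULL, requests, config = cv_config()) {
  ps <- variant$model$params
  ko <- apply_knockout(variant, params)
  base_params <- if (is.null(params)) ps$reference else {
    p <- params
    if (is.null(names(p))) names(p) <- ps$names
    p[ps$names]
  }
  base_params <- stats::setNames(as.double(base_params), ps$names)
  mask <- ko$mask
  h <- config$fd_step

  f0 <- variant_features(variant, base_params, requests, config)
  G <- matrix(0, length(requests), ps$size,
              dimnames = list(names(f0), ps$names))
  for (l in which(mask)) {
    kp <- base_params
    km <- base_params
    kp[l] <- kp[l] * exp(h)
    km[l] <- km[l] * exp(-h)
    fp <- tryCatch(
      variant_features(variant, kp, requests, config),
      cv_error = function(e) {
        abort_sensitivity(paste0(
          "Feature evaluation failed under +perturbation of '", ps$names[l], "': ",
          conditionMessage(e)
        ))
      }
    )
    fm <- tryCatch(
      variant_features(variant, km, requests, config),
      cv_error = function(e) {
        abort_sensitivity(paste0(
          "Feature evaluation failed under -perturbation of '", ps$names[l], "': ",
          conditionMessage(e)
        ))
      }
    )
    G[, l] <- (fp - fm) / (2 * h)
  }
  list(values = f0, gradients = G, mask = mask)
}

# ---------------------------------------------------------------------
# Public sensitivity operations

#' Sensitivity of the solution to logged parameters
#'
#' Central finite differences of the full solution with respect to each
#' logged parameter: `d g_j(t_i) / d log k_l`.  Transient and entrained
#' variants are sampled at fixed external times; free-running periodic
#' variants are re-anchored per perturbation and sampled at fixed phase
#' fractions of their own cycle (`times` then are fractions in `[0, 1)`).
#'
#' @param variant A [ge_variant()].
#' @param params Named parameter vector (defaults to reference values).
#' @param times Sampling times (external time, or phase fractions for
#'   free-running variants).
#' @param config A [cv_config()] list (`fd_step`).
#' @return An object of class `cv_sensitivity`: list with `array`
#'   (`time x variable x parameter`, masked parameter slices exactly
#'   zero), `times`, `mask`, `variant_id`, `method` metadata.
#' @export
solution_sensitivity <- function(variant, params = NULL, times, config = cv_config()) {
  ps <- variant$model$params
  ko <- apply_knockout(variant, params)
  base_params <- stats::setNames(ko$params, ps$names)
  # knockouts were zeroed in ko$params; but FD needs original positives for
  # perturbable entries only, so start from reference/user values:
  base <- if (is.null(params)) ps$reference else {
    p <- params
    if (is.null(names(p))) names(p) <- ps$names
    as.double(p[ps$names])
  }
  base <- stats::setNames(base, ps$names)
  mask <- ko$mask
  h <- config$fd_step

  sample_states <- function(k) {
    if (variant$solution_kind == "transient") {
      grid <- sort(unique(c(transient_grid(variant, config), times)))
      traj <- integrate_variant(variant, k, grid, config = config)
      traj$states[match(times, grid), , drop = FALSE]
    } else if (variant$entrained) {
      orbit <- find_periodic_orbit(variant, k, config)
      one <- orbit$one_period
      t(vapply(times, function(tt) {
        vapply(seq_len(ncol(one$states)), function(j) {
          spline_at(one$times, one$states[, j], tt)
        }, numeric(1))
      }, numeric(ncol(one$states))))
    } else {
      if (any(times < 0 | times >= 1)) {
        abort_input("Free-running sensitivity times are phase fractions in [0, 1).")
      }
      orbit <- find_periodic_orbit(variant, k, config)
      one <- orbit$one_period
      t(vapply(times * orbit$period, function(tt) {
        vapply(seq_len(ncol(one$states)), function(j) {
          spline_at(one$times, one$states[, j], tt)
        }, numeric(1))
      }, numeric(ncol(one$states))))
    }
  }

  n <- variant$model$n
  arr <- array(0, dim = c(length(times), n, ps$size),
               dimnames = list(NULL, variant$model$state_names, ps$names))
  for (l in which(mask)) {
    kp <- base; km <- base
    kp[l] <- kp[l] * exp(h)
    km[l] <- km[l] * exp(-h)
    sp <- tryCatch(sample_states(kp), cv_error = function(e) {
      abort_sensitivity(paste0("Perturbed integration failed for '", ps$names[l], "': ",
                               conditionMessage(e)))
    })
    sm <- tryCatch(sample_states(km), cv_error = function(e) {
      abort_sensitivity(paste0("Perturbed integration failed for '", ps$names[l], "': ",
                               conditionMessage(e)))
    })
    arr[, , l] <- (sp - sm) / (2 * h)
  }
  structure(
    list(
      array = arr, times = times, mask = mask,
      variant_id = variant$id,
      method = list(scheme = "central log-FD", step = h)
    ),
    class = "cv_sensitivity"
  )
}

#' @export
print.cv_sensitivity <- function(x, ...) {
  d <- dim(x$array)
  cat("<cv_sensitivity> variant '", x$variant_id, "': ",
      d[1], " times x ", d[2], " variables x ", d[3], " parameters\n", sep = "")
  invisible(x)
}

#' Raw level gradient from a sensitivity tensor
#'
#' Exact row extraction at `(j, t)`; requesting a time not on the
#' tensor's grid is an error (no silent interpolation).
#'
#' @param tensor A `cv_sensitivity` from [solution_sensitivity()].
#' @param j Variable index.
#' @param t Sampling time (must be on the tensor grid).
#' @return Named numeric vector over the parameter axis.
#' @export
level_gradient <- function(tensor, j, t) {
  if (!inherits(tensor, "cv_sensitivity")) abort_input("`tensor` must be a cv_sensitivity.")
  i <- match_time(tensor$times, t)
  stats::setNames(tensor$array[i, j, ], dimnames(tensor$array)[[3]])
}

#' Raw period gradient of a periodic variant
#'
#' Central finite differences of the measured period in logged
#' parameters.  Entrained variants return the zero vector flagged
#' `entrained = TRUE` (their period is locked to the forcing), so mixed
#' catalogues remain processable.
#'
#' @inheritParams solution_sensitivity
#' @return Named numeric vector over the parameter axis, with attribute
#'   `entrained`.
#' @export
period_gradient <- function(variant, params = NULL, config = cv_config()) {
  if (variant$solution_kind != "periodic") {
    abort_input("`period_gradient` requires a periodic variant.")
  }
  if (variant$entrained) {
    g <- stats::setNames(rep(0, variant$model$params$size), variant$model$params$names)
    attr(g, "entrained") <- TRUE
    return(g)
  }
  fg <- feature_gradients(variant, params, list(feature_request("tau", "period")), config)
  g <- fg$gradients["tau", ]
  attr(g, "entrained") <- FALSE
  g
}

#' Raw peak-time gradient
#'
#' Gradient of the parabola-refined time of the `n`-th peak of variable
#' `j`, by central finite differences in logged parameters.  A flat or
#' missing peak raises a degenerate-peak error.
#'
#' @inheritParams solution_sensitivity
#' @param j Variable index.
#' @param n Peak index (1-based; default 1).
#' @return Named numeric vector over the parameter axis.
#' @export
peak_time_gradient <- function(variant, params = NULL, j = 1, n = 1,
                               config = cv_config()) {
  fg <- feature_gradients(
    variant, params,
    list(feature_request("phi", "peak_time", j = j, n1 = n)), config
  )
  fg$gradients["phi", ]
}

#' Raw amplitude gradient
#'
#' Gradient of the peak-to-trough amplitude (max minus min of variable
#' `j` over one anchored period, or over the horizon for transients).
#'
#' @inheritParams peak_time_gradient
#' @return Named numeric vector over the parameter axis.
#' @export
amplitude_gradient <- function(variant, params = NULL, j = 1, config = cv_config()) {
  fg <- feature_gradients(
    variant, params,
    list(feature_request("amp", "amplitude", j = j)), config
  )
  fg$gradients["amp", ]
}

#' Raw fall-ratio gradient
#'
#' Gradient of `R_j = g_j(phi_j + delta) / g_j(phi_j)` where `phi_j` is
#' the refined time of the `n`-th peak of variable `j`; the config
#' switch `fall_ratio_side` selects the post-peak (default) or pre-peak
#' offset.
#'
#' @inheritParams peak_time_gradient
#' @param delta Time offset from the peak (model time units).
#' @return Named numeric vector over the parameter axis.
#' @export
fall_ratio_gradient <- function(variant, params = NULL, j = 1, delta = 2,
                                n = 1, config = cv_config()) {
  fg <- feature_gradients(
    variant, params,
    list(feature_request("fr", "fall_ratio", j = j, delta = delta, n1 = n)), config
  )
  fg$gradients["fr", ]
}

#' Raw peak-level-ratio gradient
#'
#' Gradient of `L_n2 / L_n1`, the ratio of refined levels of the
#' `n2`-th to the `n1`-th peak of variable `j`.
#'
#' @inheritParams peak_time_gradient
#' @param n1,n2 Peak indices (1-based).
#' @return Named numeric vector over the parameter axis.
#' @export
peak_ratio_gradient <- function(variant, params = NULL, j = 1, n2 = 2, n1 = 1,
                                config = cv_config()) {
  fg <- feature_gradients(
    variant, params,
    list(feature_request("pr", "peak_ratio", j = j, n1 = n1, n2 = n2)), config
  )
  fg$gradients["pr", ]
}
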