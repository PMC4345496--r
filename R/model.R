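# Parametrized ODE models and their GE-variants.
#
# A model couples a vector field f(t, x, k, u) (u = scalar external input
# from the variant's schedule) with a parameter space of strictly
# positive reference rates.  A GE-variant pairs the model with a genetic
# background (knockouts: rates forced to exactly zero and removed from
# the perturbable axis) and an environmental condition (a piecewise-
# constant input schedule, repeating or one-shot), and declares which
# solution is of interest: an attracting periodic orbit or a transient
# from a given initial state.

#' Define a parameter space
#'
#' @param reference Named numeric vector of strictly positive reference
#'   parameter values (original scale; perturbations act on their logs).
#' @param fixed Character vector of parameter names excluded from
#'   perturbation (e.g. Hill exponents whose values were never fitted).
#' @return A list of class `cv_parameter_space` with `names`,
#'   `reference`, `size` and `fixed`.
#' @export
parameter_space <- function(reference, fixed = character()) {
  if (is.null(names(reference)) || any(names(reference) == "")) {
    abort_input("`reference` must be a fully named numeric vector.")
  }
  if (anyDuplicated(names(reference))) {
    abort_input("Parameter names must be unique.")
  }
  if (any(!is.finite(reference)) || any(reference <= 0)) {
    abort_input("All reference parameter values must be strictly positive (logs must exist).")
  }
  if (!all(fixed %in% names(reference))) {
    abort_input("`fixed` contains names not in the parameter space.")
  }
  structure(
    list(
      names = names(reference),
      reference = stats::setNames(as.double(reference), names(reference)),
      size = length(reference),
      fixed = fixed
    ),
    class = "cv_parameter_space"
  )
}

#' Define an ODE model
#'
#' @param name Model name (used by the registry and in reports).
#' @param rhs Vector field `function(t, x, k, u)` returning the state
#'   derivative; `k` is the named parameter vector on the original scale
#'   and `u` the scalar input level at time `t`.
#' @param state_names Names of the state variables.
#' @param params A [parameter_space()].
#' @param time_unit Time unit of the model (metadata only; never
#'   converted implicitly).
#' @param nominal_period Rough period of the oscillation at the reference
#'   parameters, used only to size settle horizons.
#' @param default_x0 Default initial state for periodic variants.
#' @return A list of class `cv_model`.
#' @export
ode_model <- function(name, rhs, state_names, params, time_unit = "h",
                      nominal_period = NULL, default_x0 = NULL) {
  if (!inherits(params, "cv_parameter_space")) {
    abort_input("`params` must be a cv_parameter_space.")
  }
  if (is.null(default_x0)) default_x0 <- rep(1, length(state_names))
  if (length(default_x0) != length(state_names)) {
    abort_input("`default_x0` length must match `state_names`.")
  }
  structure(
    list(
      name = name, rhs = rhs, state_names = state_names,
      n = length(state_names), params = params,
      time_unit = time_unit, nominal_period = nominal_period,
      default_x0 = as.double(default_x0)
    ),
    class = "cv_model"
  )
}

#' Define an input schedule
#'
#' Piecewise-constant external input.  Segments are right-open intervals
#' `[start, end)`; outside all segments the input is `default_level`.
#' With a `period`, the schedule repeats (time is taken modulo the
#' period); without one it is one-shot.
#'
#' @param segments A data frame with columns `start`, `end`, `level`
#'   (non-overlapping, increasing), or `NULL` for a constant input.
#' @param period Repeat period, or `NULL` for a one-shot schedule.
#' @param default_level Input level outside the segments.
#' @return A list of class `cv_schedule`.
#' @export
#' @examples
#' light_12_12 <- input_schedule(
#'   data.frame(start = 0, end = 12, level = 1),
#'   period = 24, default_level = 0
#' )
input_schedule <- function(segments = NULL, period = NULL, default_level = 0) {
  if (!is.null(segments)) {
    segments <- tibble::as_tibble(segments)
    req <- c("start", "end", "level")
    if (!all(req %in% names(segments))) {
      abort_input("`segments` needs columns start, end, level.")
    }
    if (any(segments$end <= segments$start)) {
      abort_input("Schedule segments must have end > start.")
    }
    segments <- dplyr::arrange(segments, .data$start)
    if (nrow(segments) > 1 &&
        any(segments$start[-1] < segments$end[-nrow(segments)])) {
      abort_input("Schedule segments must not overlap.")
    }
    if (!is.null(period) && any(segments$end > period)) {
      abort_input("Repeating schedule segments must lie within [0, period].")
    }
  }
  structure(
    list(segments = segments, period = period, default_level = default_level),
    class = "cv_schedule"
  )
}

# Input level at time t (vectorized over t).
schedule_level <- function(schedule, t) {
  if (is.null(schedule) || is.null(schedule$segments)) {
    lv <- if (is.null(schedule)) 0 else schedule$default_level
    return(rep(lv, length(t)))
  }
  tt <- t
  if (!is.null(schedule$period)) tt <- tt %% schedule$period
  out <- rep(schedule$default_level, length(t))
  for (i in seq_len(nrow(schedule$segments))) {
    seg <- schedule$segments[i, ]
    out[tt >= seg$start & tt < seg$end] <- seg$level
  }
  out
}

# Breakpoints of a schedule inside [t0, t1] (for segment-wise restarts).
schedule_breaks <- function(schedule, t0, t1) {
  if (is.null(schedule) || is.null(schedule$segments)) return(numeric(0))
  br <- sort(unique(c(schedule$segments$start, schedule$segments$end)))
  if (!is.null(schedule$period)) {
    p <- schedule$period
    reps <- seq(floor(t0 / p), ceiling(t1 / p))
    br <- sort(unique(as.vector(outer(br, reps * p, `+`))))
  }
  br[br > t0 & br < t1]
}

#' Define a GE-variant of a model
#'
#' A GE-variant is one combination of genetic background and
#' environmental condition: it carries the input schedule, the knockout
#' set (rates set to exactly zero and excluded from the perturbable
#' logged-parameter axis), optional additional mask ids (e.g. parameters
#' of a dead sub-network), and whether the solution of interest is an
#' attracting periodic orbit or a transient from `x0`.
#'
#' @param model A [ode_model()].
#' @param id Variant identifier.
#' @param solution_kind `"periodic"` or `"transient"`.
#' @param schedule A [input_schedule()] (or `NULL` for constant
#'   `default_level = 0` input).  A periodic variant with a repeating
#'   schedule is treated as entrained: its period is locked to the
#'   forcing period.
#' @param knockouts Parameter names forced to zero.
#' @param masked Additional parameter names masked in linearized
#'   constraints (declared, not inferred).
#' @param x0 Initial state (required for transient variants).
#' @param horizon Time length of interest (required for transient
#'   variants).
#' @return A list of class `cv_variant`.
#' @export
ge_variant <- function(model, id, solution_kind = c("periodic", "transient"),
                       schedule = NULL, knockouts = character(),
                       masked = character(), x0 = NULL, horizon = NULL) {
  solution_kind <- match.arg(solution_kind)
  if (!inherits(model, "cv_model")) abort_input("`model` must be a cv_model.")
  pn <- model$params$names
  bad <- setdiff(knockouts, pn)
  if (length(bad) > 0) {
    abort_input(paste0("Unknown knockout parameter(s): ", paste(bad, collapse = ", ")))
  }
  bad <- setdiff(masked, pn)
  if (length(bad) > 0) {
    abort_input(paste0("Unknown masked parameter(s): ", paste(bad, collapse = ", ")))
  }
  if (solution_kind == "transient") {
    if (is.null(x0)) abort_input("Transient variants require `x0`.")
    if (length(x0) != model$n) {
      abort_input(sprintf("`x0` must have length %d (one value per state).", model$n))
    }
    if (is.null(horizon)) abort_input("Transient variants require `horizon`.")
  }
  entrained <- solution_kind == "periodic" &&
    !is.null(schedule) && !is.null(schedule$period)
  structure(
    list(
      model = model, id = id, solution_kind = solution_kind,
      schedule = schedule, knockouts = knockouts, masked = masked,
      x0 = if (is.null(x0)) NULL else as.double(x0),
      horizon = horizon, entrained = entrained
    ),
    class = "cv_variant"
  )
}

#' Apply a variant's knockouts to a parameter vector
#'
#' Sets knocked-out rates to exactly zero and returns the perturbable
#' mask: `FALSE` at knockouts, at the parameter space's fixed parameters,
#' and at the variant's declared extra masked ids.  Downstream
#' linearizations carry exact zeros at all masked coordinates.
#'
#' @param variant A [ge_variant()].
#' @param params Named parameter vector (defaults to the model's
#'   reference values).
#' @return A list with `params` (knockouts zeroed) and `mask` (named
#'   logical vector, `TRUE` = perturbable).
#' @export
apply_knockout <- function(variant, params = NULL) {
  if (!inherits(variant, "cv_variant")) abort_input("`variant` must be a cv_variant.")
  ps <- variant$model$params
  if (is.null(params)) params <- ps$reference
  if (is.null(names(params))) {
    if (length(params) != ps$size) abort_input("`params` must be named or of full length.")
    names(params) <- ps$names
  }
  if (!all(ps$names %in% names(params))) {
    abort_input("`params` is missing parameters of the model's space.")
  }
  params <- params[ps$names]
  params[variant$knockouts] <- 0
  mask <- stats::setNames(rep(TRUE, ps$size), ps$names)
  mask[variant$knockouts] <- FALSE
  mask[ps$fixed] <- FALSE
  mask[variant$masked] <- FALSE
  list(params = stats::setNames(as.double(params), ps$names), mask = mask)
}

#' Integrate a GE-variant
#'
#' Integrates the variant's vector field over a requested time grid with
#' an adaptive stiff integrator, restarting at every schedule
#' discontinuity so that input switches are applied exactly at segment
#' boundaries.
#'
#' @param variant A [ge_variant()].
#' @param params Named parameter vector (original scale; knockouts are
#'   applied on top).  Defaults to the reference values.
#' @param times Strictly increasing output time grid.
#' @param x0 Initial state at `times[1]` (defaults to the variant's `x0`,
#'   falling back to the model default for periodic variants).
#' @param config A [cv_config()] list (integrator tolerances).
#' @return An object of class `cv_trajectory`: list with `times`,
#'   `states` (length(times) x n matrix), `variant_id`, `params`.
#'   Coerce with `as_tibble()`.
#' @export
integrate_variant <- function(variant, params = NULL, times, x0 = NULL,
                              config = cv_config()) {
  if (!inherits(variant, "cv_variant")) abort_input("`variant` must be a cv_variant.")
  if (length(times) < 2 || any(diff(times) <= 0)) {
    abort_input("`times` must be strictly increasing with at least two points.")
  }
  ko <- apply_knockout(variant, params)
  k <- stats::setNames(ko$params, variant$model$params$names)
  if (is.null(x0)) {
    x0 <- if (!is.null(variant$x0)) variant$x0 else variant$model$default_x0
  }
  if (length(x0) != variant$model$n) {
    abort_input(sprintf("`x0` must have length %d (one value per state).", variant$model$n))
  }
  rhs <- variant$model$rhs
  sched <- variant$schedule

  deriv <- function(t, x, parms) {
    list(rhs(t, x, k, schedule_level(sched, t)))
  }

  t0 <- times[1]
  t1 <- times[length(times)]
  breaks <- schedule_breaks(sched, t0, t1)
  bounds <- c(t0, breaks, t1)
  states <- matrix(NA_real_, length(times), variant$model$n)
  states[1, ] <- x0
  x <- as.double(x0)
  for (seg in seq_len(length(bounds) - 1)) {
    a <- bounds[seg]
    b <- bounds[seg + 1]
    inner <- times[times > a & times <= b]
    grid <- unique(c(a, inner, b))
    if (length(grid) < 2) next
    sol <- tryCatch(
      deSolve::lsoda(y = x, times = grid, func = deriv, parms = NULL,
                     rtol = config$rtol, atol = config$atol),
      warning = function(w) {
        abort_integration(paste0("Integrator warning in variant '", variant$id, "': ",
                                 conditionMessage(w)))
      },
      error = function(e) {
        abort_integration(paste0("Integration failed in variant '", variant$id, "': ",
                                 conditionMessage(e)))
      }
    )
    vals <- sol[, -1, drop = FALSE]
    if (!all(is.finite(vals))) {
      abort_integration(paste0("Non-finite state encountered in variant '", variant$id, "'."))
    }
    if (length(inner) > 0) {
      states[match(inner, times), ] <- vals[match(inner, grid), , drop = FALSE]
    }
    x <- vals[nrow(vals), ]
  }
  colnames(states) <- variant$model$state_names
  structure(
    list(times = times, states = states, variant_id = variant$id, params = k),
    class = "cv_trajectory"
  )
}

#' @export
print.cv_trajectory <- function(x, ...) {
  cat("<cv_trajectory> variant '", x$variant_id, "', ",
      length(x$times), " time points, ", ncol(x$states), " variables\n", sep = "")
  invisible(x)
}

#' @method as_tibble cv_trajectory
#' @export
as_tibble.cv_trajectory <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(time = x$times), tibble::as_tibble(x$states))
}
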