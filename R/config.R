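#' Numerical configuration for constraint-value analyses
#'
#' Collects every tolerance and numerical knob used by the integrators,
#' the limit-cycle detector, the finite-difference sensitivity scheme and
#' the linear-algebra layer into one list, so a whole analysis can be
#' reproduced from a single configuration record.  All values are logged
#' into pipeline reports.
#'
#' @param rtol,atol Relative/absolute tolerance of the stiff adaptive
#'   integrator used for sensitivity work.  Defaults `1e-9` / `1e-12`;
#'   use [cv_config_exploratory()] for quick looks.
#' @param settle_periods Number of nominal periods integrated before the
#'   limit-cycle (or entrained-cycle) detector starts measuring returns.
#' @param n_return_intervals Number of trailing return intervals averaged
#'   to estimate the period.
#' @param return_rel_tol Maximum relative spread allowed between successive
#'   return intervals for the orbit to count as converged.
#' @param closure_tol Maximum distance (relative to state scale) between
#'   states one period apart.
#' @param amplitude_floor Oscillation amplitude (max minus min over the
#'   measuring window) below which a periodic variant is declared
#'   non-oscillating.
#' @param steps_per_period Output-grid resolution used when measuring
#'   periodic orbits.
#' @param transient_steps_per_period Output-grid resolution of transient
#'   feature evaluation, per nominal period of the model (capped at
#'   20000 points per trajectory).
#' @param fd_step Central finite-difference step `h` in logged parameters:
#'   parameters are perturbed multiplicatively by `exp(+-h)`.
#' @param prominence_frac Peaks whose prominence (height above the higher
#'   of the two flanking minima) is below this fraction of the signal range
#'   are discarded by the peak detector.
#' @param curvature_floor Minimum `|second derivative|` at a refined peak
#'   (relative to `range/span^2`) below which peak-time features are
#'   declared degenerate.
#' @param dependence_tol A residual norm below `dependence_tol * max row
#'   norm` is treated as exact linear dependence (constraint value 0).
#' @param spectral_tol Singular values below `spectral_tol * sigma_1` are
#'   treated as zero when counting numerical rank.
#' @param fall_ratio_offset Default time offset `Delta` used by fall-ratio
#'   features (model time units).
#' @param fall_ratio_side `"after"` (default) or `"before"`: whether the
#'   fall ratio compares the level `Delta` after or before the peak.
#'
#' @return A named list with class `cv_config`.
#' @seealso [read_cv_config()] to load the same settings from a YAML file.
#' @export
#' @examples
#' cfg <- cv_config(settle_periods = 10)
#' cfg$rtol
cv_config <- function(rtol = 1e-9,
                      atol = 1e-12,
                      settle_periods = 20,
                      n_return_intervals = 5,
                      return_rel_tol = 1e-6,
                      closure_tol = 1e-6,
                      amplitude_floor = 1e-4,
                      steps_per_period = 4000,
                      transient_steps_per_period = 1000,
                      fd_step = 1e-3,
                      prominence_frac = 1e-4,
                      curvature_floor = 1e-8,
                      dependence_tol = 1e-10,
                      spectral_tol = 1e-12,
                      fall_ratio_offset = 2,
                      fall_ratio_side = c("after", "before")) {
  fall_ratio_side <- match.arg(fall_ratio_side)
  cfg <- list(
    rtol = rtol, atol = atol,
    settle_periods = settle_periods,
    n_return_intervals = n_return_intervals,
    return_rel_tol = return_rel_tol,
    closure_tol = closure_tol,
    amplitude_floor = amplitude_floor,
    steps_per_period = steps_per_period,
    transient_steps_per_period = transient_steps_per_period,
    fd_step = fd_step,
    prominence_frac = prominence_frac,
    curvature_floor = curvature_floor,
    dependence_tol = dependence_tol,
    spectral_tol = spectral_tol,
    fall_ratio_offset = fall_ratio_offset,
    fall_ratio_side = fall_ratio_side
  )
  structure(cfg, class = "cv_config")
}

#' @describeIn cv_config Looser integrator tolerances (1e-6/1e-9) for
#'   exploratory runs where sensitivity-grade accuracy is not needed.
#' @export
cv_config_exploratory <- function(...) {
  cv_config(rtol = 1e-6, atol = 1e-9, ...)
}

#' Read a configuration from a YAML file
#'
#' Keys absent from the file keep their [cv_config()] defaults; unknown
#' keys are an error so that typos do not silently fall back to defaults.
#'
#' @param path Path to a YAML file of `key: value` pairs.
#' @return A `cv_config` list.
#' @export
read_cv_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(cv_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0) {
    abort_input(paste0("Unknown config keys: ", paste(bad, collapse = ", ")))
  }
  do.call(cv_config, vals)
}
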