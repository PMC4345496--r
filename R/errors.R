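# Condition classes used across the package.  Every user-facing error is an
# rlang condition with a cv_* class so callers can handle failure modes
# (bad input vs. solver breakdown vs. degenerate geometry) separately.

cv_abort <- function(message, class, ...) {
  rlang::abort(message, class = c(class, "cv_error"), ...)
}

abort_input <- function(message, ...) {
  cv_abort(message, "cv_input_error", ...)
}

abort_integration <- function(message, ...) {
  cv_abort(message, "cv_integration_error", ...)
}

abort_no_oscillation <- function(message, ...) {
  cv_abort(message, "cv_no_oscillation_error", ...)
}

abort_not_converged <- function(message, ...) {
  cv_abort(message, "cv_not_converged_error", ...)
}

abort_sensitivity <- function(message, ...) {
  cv_abort(message, "cv_sensitivity_error", ...)
}

abort_degenerate_peak <- function(message, ...) {
  cv_abort(message, "cv_degenerate_peak_error", ...)
}

abort_rank <- function(message, ...) {
  cv_abort(message, "cv_rank_error", ...)
}
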