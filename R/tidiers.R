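# broom-style tidiers for the result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an ordering result
#'
#' @param x A `cv_ordering`.
#' @param ... Unused.
#' @return Tibble with columns `rank`, `id`, `orig_index`, `value`.
#' @method tidy cv_ordering
#' @export
tidy.cv_ordering <- function(x, ...) x$ordering

#' One-row summary of an ordering result
#'
#' @param x A `cv_ordering`.
#' @param ... Unused.
#' @return Tibble with `m`, `s`, `rank` (positive values), `v_top`,
#'   `n_effective_absolute` (`v >= 1`), `n_effective_relative`
#'   (`v > 1%` of top), `n_ties`.
#' @method glance cv_ordering
#' @export
glance.cv_ordering <- function(x, ...) {
  eff <- effective_constraints(x)
  tibble::tibble(
    m = x$m, s = x$s,
    rank = sum(x$values > 0),
    v_top = x$values[1],
    n_effective_absolute = sum(eff$effective_absolute),
    n_effective_relative = sum(eff$effective_relative),
    n_ties = length(x$ties)
  )
}

#' Tidy a spectral report
#'
#' @param x A `cv_spectrum`.
#' @param ... Unused.
#' @return Tibble with `index`, `sigma`, `eigen_fim` (`sigma^2`).
#' @method tidy cv_spectrum
#' @export
tidy.cv_spectrum <- function(x, ...) {
  tibble::tibble(
    index = seq_along(x$singular_values),
    sigma = x$singular_values,
    eigen_fim = x$singular_values^2
  )
}

#' One-row summary of a spectral report
#'
#' @param x A `cv_spectrum`.
#' @param ... Unused.
#' @return Tibble with `m`, `s`, `rank`, `sigma_max`, `sigma_min_pos`,
#'   `condition`.
#' @method glance cv_spectrum
#' @export
glance.cv_spectrum <- function(x, ...) {
  tibble::tibble(
    m = x$m, s = x$s, rank = x$rank,
    sigma_max = x$singular_values[1],
    sigma_min_pos = if (x$rank > 0) x$positive[x$rank] else NA_real_,
    condition = x$condition
  )
}

#' Tidy a transition report
#'
#' @param x A `cv_transition`.
#' @param ... Unused.
#' @return Tibble with one row per singular value: `index`,
#'   `sigma_before` (`NA` for the appended one), `sigma_after`.
#' @method tidy cv_transition
#' @export
tidy.cv_transition <- function(x, ...) {
  tibble::tibble(
    index = seq_len(x$m + 1),
    sigma_before = c(x$sigma_before, NA_real_),
    sigma_after = x$sigma_after
  )
}

#' One-row summary of a transition report
#'
#' @param x A `cv_transition`.
#' @param ... Unused.
#' @return Tibble with `value`, `interlacing_ok`, `new_smallest_ok`,
#'   `condition_ok`, `condition_before`, `condition_after`.
#' @method glance cv_transition
#' @export
glance.cv_transition <- function(x, ...) {
  tibble::tibble(
    value = x$value,
    interlacing_ok = x$interlacing_ok,
    new_smallest_ok = x$new_smallest_ok,
    condition_ok = x$condition_ok,
    condition_before = x$condition_before,
    condition_after = x$condition_after
  )
}

#' Tidy a sensitivity tensor
#'
#' @param x A `cv_sensitivity`.
#' @param ... Unused.
#' @return Long tibble with columns `time`, `variable`, `parameter`,
#'   `sensitivity`.
#' @method tidy cv_sensitivity
#' @export
tidy.cv_sensitivity <- function(x, ...) {
  d <- dim(x$array)
  dn <- dimnames(x$array)
  tibble::tibble(
    time = rep(x$times, times = d[2] * d[3]),
    variable = rep(rep(dn[[2]], each = d[1]), times = d[3]),
    parameter = rep(dn[[3]], each = d[1] * d[2]),
    sensitivity = as.vector(x$array)
  )
}
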