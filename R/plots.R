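# Value-vs-rank and spectrum figures.

#' Plot ordered constraint values against rank
#'
#' Open circles on a log value axis: the standard picture of an ordered
#' sloppy constraint set, where approximately geometric decay appears as
#' a straight line.  Zero values (linearly dependent constraints) are
#' omitted from the log plot and reported in the subtitle.
#'
#' @param object A `cv_ordering`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cv_ordering
#' @export
autoplot.cv_ordering <- function(object, ...) {
  d <- object$ordering
  pos <- d[d$value > 0, , drop = FALSE]
  n_zero <- sum(d$value == 0)
  ggplot2::ggplot(pos, ggplot2::aes(x = .data$rank, y = .data$value)) +
    ggplot2::geom_point(shape = 1, size = 2) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "rank", y = "constraint value v",
      title = "Ordered constraint values",
      subtitle = if (n_zero > 0) paste0(n_zero, " dependent constraint(s) with v = 0 omitted") else NULL
    ) +
    ggplot2::theme_minimal()
}

#' Plot a singular spectrum
#'
#' @param object A `cv_spectrum`.
#' @param ... Unused.
#' @return A ggplot of singular values (log scale) against index.
#' @method autoplot cv_spectrum
#' @export
autoplot.cv_spectrum <- function(object, ...) {
  d <- tidy.cv_spectrum(object)
  d <- d[d$sigma > 0, , drop = FALSE]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$index, y = .data$sigma)) +
    ggplot2::geom_point(shape = 1, size = 2) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "index", y = expression(sigma[i]),
                  title = "Singular spectrum of the constraint matrix") +
    ggplot2::theme_minimal()
}

#' Plot a trajectory
#'
#' @param object A `cv_trajectory`.
#' @param vars Variables to show (default all).
#' @param ... Unused.
#' @return A ggplot of state levels over time.
#' @method autoplot cv_trajectory
#' @export
autoplot.cv_trajectory <- function(object, vars = NULL, ...) {
  tbl <- tibble::as_tibble(object)
  long <- tidyr::pivot_longer(tbl, -"time", names_to = "variable", values_to = "level")
  if (!is.null(vars)) long <- long[long$variable %in% vars, , drop = FALSE]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$level,
                                     colour = .data$variable)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time", y = "level", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot rank trajectories across perturbed parameter sets
#'
#' @param object A `cv_rank_stability`.
#' @param top_n Show constraints whose reference rank is at most this.
#' @param ... Unused.
#' @return A ggplot: rank (reversed axis) per draw, one line per
#'   constraint.
#' @method autoplot cv_rank_stability
#' @export
autoplot.cv_rank_stability <- function(object, top_n = object$top_n, ...) {
  base_ids <- object$ranks$id[object$ranks$draw == 0 & object$ranks$rank <= top_n]
  d <- object$ranks[object$ranks$id %in% base_ids, , drop = FALSE]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$draw, y = .data$rank,
                                  colour = .data$id, group = .data$id)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "parameter draw (0 = reference)", y = "rank",
                  title = "Rank stability under parameter perturbation") +
    ggplot2::theme_minimal()
}
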