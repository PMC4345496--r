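# Optimization-geometry layer: the Fisher information matrix F = M^T M of
# the quadratic objective sum_i (C_i(k) - target_i)^2 / se_i^2, its
# singular spectrum, and what happens to the spectrum when one constraint
# row is added (interlacing, new smallest singular value, condition-number
# bound).

#' Fisher information matrix of a constraint set
#'
#' For a constraint matrix `M` of se-normalized linearized constraints,
#' `F = M^T M` is both the Hessian of the quadratic objective at its
#' optimum and the Fisher information matrix of the associated artificial
#' Gaussian likelihood.  Its eigenvalues are the squared singular values
#' of `M`; its inverse (on the constrained subspace) approximates the
#' posterior covariance and gives the Cramer-Rao bound.
#'
#' @param x Constraint-matrix tibble or numeric matrix.
#' @return A symmetric positive semidefinite s x s matrix with the
#'   parameter axis as dimnames.
#' @export
#' @examples
#' build_fim(rbind(c(2, 0)))    # diag(4, 0)
build_fim <- function(x) {
  M <- cm_resolve(x)
  F <- crossprod(M)
  (F + t(F)) / 2 # enforce exact symmetry
}

#' Singular spectrum of a constraint matrix
#'
#' @param x Constraint-matrix tibble or numeric matrix.
#' @param config A [cv_config()] list; `spectral_tol` sets the zero
#'   threshold for the numerical rank.
#' @return An object of class `cv_spectrum`: list with `singular_values`
#'   (all `min(m, s)` of them, non-increasing), `positive` (those above
#'   `spectral_tol * sigma_1`), `rank`, `condition` (`sigma_1` over the
#'   smallest positive singular value), right/left singular vectors `V` /
#'   `U` (columns), `fim` (`M^T M`), and `m`, `s`.
#' @export
constraint_spectrum <- function(x, config = cv_config()) {
  M <- cm_resolve(x)
  sv <- svd(M)
  d <- sv$d
  pos <- d > config$spectral_tol * max(d, 0)
  r <- sum(pos)
  structure(
    list(
      singular_values = d,
      positive = d[pos],
      rank = r,
      condition = if (r > 0) d[1] / d[r] else NA_real_,
      U = sv$u, V = sv$v,
      fim = crossprod(M),
      params = colnames(M),
      m = nrow(M), s = ncol(M)
    ),
    class = "cv_spectrum"
  )
}

#' @export
print.cv_spectrum <- function(x, ...) {
  cat("<cv_spectrum> m = ", x$m, ", s = ", x$s, ", rank = ", x$rank, "\n", sep = "")
  cat("  sigma_1 = ", format(x$singular_values[1]),
      ", condition = ", format(x$condition), "\n", sep = "")
  invisible(x)
}

#' Spectral report for adding one constraint row
#'
#' Computes the singular spectra of `M` and of `M` augmented with one new
#' row, the constraint value `v` of the new row relative to the rows of
#' `M`, and checks the three consequences of the m -> m+1 transition:
#' Cauchy interlacing `sigma'_1 >= sigma_1 >= sigma'_2 >= ... >= sigma_m
#' >= sigma'_(m+1)`, the new-smallest bound `sigma'_(m+1) <= v`, and the
#' condition-number bound `cond(M') >= sigma_1 / min(sigma_m, v)`.  All
#' checks are recomputed from the spectra (never cached) with tolerance
#' `1e-9 * sigma_1`.
#'
#' @param x Existing constraint matrix (tibble or numeric matrix).
#' @param c_new New constraint row (numeric vector or one-row tibble).
#' @param config A [cv_config()] list.
#' @return An object of class `cv_transition`: list with `sigma_before`,
#'   `sigma_after`, `value` (v), `interlacing_ok`, `new_smallest_ok`
#'   (`sigma'_(m+1) <= v`), `condition_ok`, `condition_before/after`, and
#'   `coefficients` (the decomposition of the new row on the existing
#'   ones).
#' @export
#' @examples
#' tr <- transition_add(rbind(c(1, 0, 0)), c(0, 1, 0))
#' tr$sigma_after     # 1 1
#' tr$value           # 1
transition_add <- function(x, c_new, config = cv_config()) {
  M <- cm_resolve(x)
  v <- cm_resolve_row(c_new)
  cm_check_axis(v, M)
  dec <- decompose_constraint(v, M, config)
  val <- dec$value
  m <- nrow(M)
  # pad with exact zeros when m (or m+1) exceeds s: a tall matrix has at
  # most s positive singular values
  d_before <- c(svd(M, nu = 0, nv = 0)$d, rep(0, max(0, m - ncol(M))))
  M2 <- rbind(M, v)
  d_after <- c(svd(M2, nu = 0, nv = 0)$d, rep(0, max(0, m + 1 - ncol(M))))
  tol <- 1e-9 * max(d_before[1], d_after[1])

  # sigma'_i >= sigma_i >= sigma'_(i+1), i = 1..m
  interlacing_ok <- all(d_after[seq_len(m)] >= d_before - tol) &&
    all(d_before >= d_after[seq_len(m) + 1] - tol)
  new_smallest_ok <- d_after[m + 1] <= val + tol

  pos_b <- d_before > config$spectral_tol * max(d_before, 0)
  pos_a <- d_after > config$spectral_tol * max(d_after, 0)
  cond_before <- d_before[1] / min(d_before[pos_b])
  cond_after <- d_after[1] / min(d_after[pos_a])
  sigma_m <- d_before[m]
  denom <- min(sigma_m, val)
  cond_bound <- if (denom > 0) d_before[1] / denom else Inf
  # full condition number of M' (zero smallest -> Inf), for the bound check
  cond_after_full <- if (d_after[m + 1] > tol) d_after[1] / d_after[m + 1] else Inf
  condition_ok <- cond_after_full >= cond_bound * (1 - 1e-9) - tol

  structure(
    list(
      sigma_before = d_before,
      sigma_after = d_after,
      value = val,
      interlacing_ok = interlacing_ok,
      new_smallest_ok = new_smallest_ok,
      condition_ok = condition_ok,
      condition_before = cond_before,
      condition_after = cond_after,
      condition_bound = cond_bound,
      coefficients = dec$coefficients,
      m = m, s = ncol(M),
      tol = tol
    ),
    class = "cv_transition"
  )
}

#' @export
print.cv_transition <- function(x, ...) {
  cat("<cv_transition> m = ", x$m, " -> ", x$m + 1, "\n", sep = "")
  cat("  value of added row v = ", format(x$value), "\n", sep = "")
  cat("  interlacing: ", x$interlacing_ok,
      "; sigma'_(m+1) <= v: ", x$new_smallest_ok,
      "; condition bound: ", x$condition_ok, "\n", sep = "")
  invisible(x)
}

#' Does a new constraint improve the spectrum?
#'
#' A new constraint can only improve the condition number of the
#' constraint matrix when its constraint value exceeds the smallest
#' positive singular value of the existing matrix; otherwise it appends a
#' smaller singular value and can only worsen conditioning.
#'
#' @inheritParams transition_add
#' @return A list with `improves` (logical), `margin`
#'   (`v - sigma_min_positive`), `value` and `sigma_min`.
#' @export
improvement_verdict <- function(x, c_new, config = cv_config()) {
  M <- cm_resolve(x)
  v <- cm_resolve_row(c_new)
  cm_check_axis(v, M)
  val <- constraint_value(v, M, config)
  d <- svd(M, nu = 0, nv = 0)$d
  pos <- d > config$spectral_tol * max(d, 0)
  sigma_min <- min(d[pos])
  list(
    improves = val > sigma_min,
    margin = val - sigma_min,
    value = val,
    sigma_min = sigma_min
  )
}
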