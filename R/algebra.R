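# Constraint value, orthogonal decomposition, and the value-maximizing
# ordering of a constraint set.
#
# The constraint value of a linearized constraint c relative to rows
# c_1..c_m is the Euclidean norm of the component of c orthogonal to
# span(c_1, ..., c_m): it measures how much the constraint can still vary
# once the others are held fixed, i.e. how much new information it adds.

# Internal: minimum-norm least-squares fit of v on the rows of R.
# Returns coefficients a (length m) and residual v - R^T a.  Uses a
# truncated SVD so linearly dependent rows are handled gracefully.
ls_fit_rows <- function(v, R, spectral_tol = 1e-12) {
  m <- nrow(R)
  if (m == 0) {
    return(list(coefficients = numeric(0), residual = v))
  }
  A <- t(R) # s x m, columns span the row space
  sv <- svd(A, nu = min(dim(A)), nv = min(dim(A)))
  pos <- sv$d > spectral_tol * max(sv$d, 0)
  r <- sum(pos)
  if (r == 0) {
    return(list(coefficients = numeric(m), residual = v))
  }
  z <- crossprod(sv$u[, seq_len(r), drop = FALSE], v) / sv$d[seq_len(r)]
  a <- drop(sv$v[, seq_len(r), drop = FALSE] %*% z)
  list(coefficients = a, residual = v - drop(A %*% a))
}

#' Constraint value relative to an existing constraint set
#'
#' The constraint value `v` of a linearized constraint `c` relative to a
#' set of linearized constraints is the norm of the component of `c`
#' orthogonal to the span of the set.  `v = 0` means `c` is linearly
#' dependent on the set and adds no local information; `v = ||c||` means
#' it is orthogonal to all of them.  All vectors are assumed to be on the
#' shared logged-parameter axis and already normalized by their standard
#' errors, so `v` is non-dimensional and `v >= 1` marks a constraint whose
#' unconstrained variation exceeds its own measurement uncertainty.
#'
#' @param c_new A linearized constraint: numeric vector or one-row
#'   constraint-matrix tibble.
#' @param rows The existing set: constraint-matrix tibble, numeric matrix,
#'   or `NULL` for the empty set (then `v = ||c_new||`).
#' @param config A [cv_config()] list; `dependence_tol` controls when a
#'   residual is snapped to exactly zero.
#' @return A single non-negative number.
#' @export
#' @examples
#' constraint_value(c(3, 4, 0), NULL)                  # 5
#' constraint_value(c(1, 0, 0), rbind(c(1, 0, 0)))     # 0: dependent
constraint_value <- function(c_new, rows = NULL, config = cv_config()) {
  v <- cm_resolve_row(c_new)
  if (is.null(rows) || (is.data.frame(rows) && nrow(rows) == 0)) {
    return(vec_norm(v))
  }
  M <- cm_resolve(rows, "rows")
  cm_check_axis(v, M)
  fit <- ls_fit_rows(v, M, config$spectral_tol)
  val <- vec_norm(fit$residual)
  scale <- max(vec_norm(v), max(row_norms(M)))
  if (val < config$dependence_tol * scale) val <- 0
  val
}

#' Orthogonal decomposition of a constraint against a set
#'
#' Splits `c` into `c_perp + sum_i a_i c_i` where `c_perp` is orthogonal
#' to every row `c_i` of the set.  When the rows are linearly dependent
#' the coefficients are the minimum-norm solution.
#'
#' @inheritParams constraint_value
#' @return A list of class `cv_decomposition` with elements `c_perp`
#'   (numeric vector), `coefficients` (length m), `residual_norm`, and
#'   `value` (the residual norm after dependence snapping).
#' @export
decompose_constraint <- function(c_new, rows = NULL, config = cv_config()) {
  v <- cm_resolve_row(c_new)
  if (is.null(rows) || (is.data.frame(rows) && nrow(rows) == 0)) {
    out <- list(
      c_perp = v, coefficients = numeric(0),
      residual_norm = vec_norm(v), value = vec_norm(v)
    )
    return(structure(out, class = "cv_decomposition"))
  }
  M <- cm_resolve(rows, "rows")
  cm_check_axis(v, M)
  fit <- ls_fit_rows(v, M, config$spectral_tol)
  rn <- vec_norm(fit$residual)
  scale <- max(vec_norm(v), max(row_norms(M)))
  val <- if (rn < config$dependence_tol * scale) 0 else rn
  structure(
    list(
      c_perp = fit$residual, coefficients = fit$coefficients,
      residual_norm = rn, value = val
    ),
    class = "cv_decomposition"
  )
}

#' @export
print.cv_decomposition <- function(x, ...) {
  cat("<cv_decomposition>\n")
  cat("  residual norm (constraint value):", format(x$value), "\n")
  cat("  coefficients on existing rows:   ", length(x$coefficients), "\n")
  invisible(x)
}

#' Value-maximizing ordering of a constraint set
#'
#' Reorders the rows of a constraint matrix so that the first value is
#' maximal and the value sequence `v_1 >= v_2 >= ... >= v_m >= 0` is
#' non-increasing, where `v_i` is the constraint value of the i-th picked
#' row relative to the previously picked rows.  The greedy sweep (pick
#' the row with maximal residual norm against the span of the rows picked
#' so far, append, repeat) is equivalent to column-pivoted orthogonal
#' triangularization of the transposed matrix.  When `m` exceeds the rank
#' of the set, the remaining rows are linearly dependent on the picked
#' subset and receive value exactly 0.
#'
#' Ties (several rows with equal residual norm to within a relative
#' `1e-12`) are broken toward the lowest original index and logged in the
#' result.
#'
#' @param x Constraint-matrix tibble or numeric matrix with at least one
#'   row.
#' @param config A [cv_config()] list; `dependence_tol` controls the
#'   value-0 snap.
#' @return An object of class `cv_ordering`: a list with `ordering` (a
#'   tibble with columns `rank`, `id`, `orig_index`, `value`),
#'   `permutation` (original indices in pick order), `values`
#'   (non-increasing), `basis` (orthonormal directions accumulated by the
#'   sweep, one row per positive value), `ties` (list of tie events) and
#'   `params` (the parameter axis).  Supports [tidy()], [glance()],
#'   [autoplot()].
#' @export
#' @examples
#' M <- as_constraint_tbl(rbind(a = c(1, 0), b = c(0, 2), d = c(1, 1)))
#' ord <- order_constraints(M)
#' ord$values           # 2 1 0
#' tidy(ord)
order_constraints <- function(x, config = cv_config()) {
  M <- cm_resolve(x)
  m <- nrow(M)
  s <- ncol(M)
  ids <- rownames(M)
  if (is.null(ids)) ids <- paste0("c", seq_len(m))
  maxnorm <- max(row_norms(M))
  tol0 <- config$dependence_tol * maxnorm

  res <- M # residual of every row against the picked span
  remaining <- seq_len(m)
  perm <- integer(m)
  vals <- numeric(m)
  ties <- list()
  basis <- matrix(0, 0, s)
  colnames(basis) <- colnames(M)

  for (step in seq_len(m)) {
    norms <- row_norms(res[remaining, , drop = FALSE])
    best <- max(norms)
    tie_tol <- 1e-12 * max(best, maxnorm)
    cand <- remaining[norms >= best - tie_tol]
    pick <- min(cand)
    if (length(cand) > 1) {
      ties[[length(ties) + 1]] <- list(rank = step, candidates = ids[cand], picked = ids[pick])
    }
    v <- norms[[match(pick, remaining)]]
    if (maxnorm == 0 || v < tol0) v <- 0
    perm[step] <- pick
    vals[step] <- v
    if (v > 0) {
      q <- res[pick, ]
      if (nrow(basis) > 0) { # one re-orthogonalization pass for stability
        q <- q - drop(crossprod(basis, basis %*% q))
      }
      q <- q / vec_norm(q)
      basis <- rbind(basis, q)
      rem2 <- setdiff(remaining, pick)
      if (length(rem2) > 0) {
        proj <- drop(res[rem2, , drop = FALSE] %*% q)
        res[rem2, ] <- res[rem2, , drop = FALSE] - outer(proj, q)
      }
    }
    remaining <- setdiff(remaining, pick)
  }
  rownames(basis) <- NULL

  structure(
    list(
      ordering = tibble::tibble(
        rank = seq_len(m), id = ids[perm], orig_index = perm, value = vals
      ),
      permutation = perm,
      values = vals,
      basis = basis,
      ties = ties,
      params = colnames(M),
      m = m, s = s,
      config = list(dependence_tol = config$dependence_tol)
    ),
    class = "cv_ordering"
  )
}

#' @export
print.cv_ordering <- function(x, n = 10, ...) {
  cat("<cv_ordering> ", x$m, " constraints on ", x$s, " parameters\n", sep = "")
  cat("  top value v_1 = ", format(x$values[1]),
      "; rank (values > 0) = ", sum(x$values > 0), "\n", sep = "")
  if (length(x$ties) > 0) cat("  ", length(x$ties), " tie event(s) logged\n", sep = "")
  print(utils::head(x$ordering, n))
  invisible(x)
}

#' Screen constraints by raw norm
#'
#' Drops constraints whose norm is below a fraction of the largest norm in
#' the set.  A constraint with small norm barely varies under parameter
#' perturbation, so it is ineffective regardless of its independence from
#' the others; in large sloppy models a majority of constraints typically
#' fail a 10%-of-max screen.
#'
#' @param x Constraint-matrix tibble or numeric matrix.
#' @param frac Fraction of the maximum row norm below which a row is
#'   dropped (default 0.1).
#' @return A list of class `cv_screen` with tibbles `kept` and `dropped`
#'   (each with a `norm` column appended), the `threshold` used, and
#'   counts `n_kept` / `n_dropped`.
#' @export
screen_norms <- function(x, frac = 0.1) {
  if (!is.numeric(frac) || length(frac) != 1 || frac < 0) {
    abort_input("`frac` must be a single non-negative number.")
  }
  M <- cm_resolve(x)
  norms <- row_norms(M)
  thr <- frac * max(norms)
  keep <- norms >= thr
  tbl <- if (is.data.frame(x)) tibble::as_tibble(x) else as_constraint_tbl(M)
  tbl$norm <- norms
  structure(
    list(
      kept = tbl[keep, , drop = FALSE],
      dropped = tbl[!keep, , drop = FALSE],
      frac = frac, threshold = thr,
      n_kept = sum(keep), n_dropped = sum(!keep)
    ),
    class = "cv_screen"
  )
}

#' @export
print.cv_screen <- function(x, ...) {
  cat("<cv_screen> kept ", x$n_kept, ", dropped ", x$n_dropped,
      " (norm < ", format(x$threshold), ")\n", sep = "")
  invisible(x)
}

#' Effective subset of an ordered constraint set
#'
#' Applies the two cut-offs used to decide how many ordered constraints
#' carry real information.  On the se-normalized scale there is a natural
#' absolute cut-off at `v_i >= 1`: below it, the unconstrained variation
#' the constraint could remove is smaller than the uncertainty of its own
#' target.  The relative rule keeps constraints whose value is higher than
#' 1% of the top ordered value.
#'
#' @param ordering A `cv_ordering` from [order_constraints()], or a
#'   numeric vector of non-increasing values.
#' @param mode `"absolute"` (keep `v_i >= 1`), `"relative"` (keep
#'   `v_i > 0.01 * v_1`) or `"both"` (default; report both flags).
#' @return A tibble with columns `rank`, `value` (plus `id` when
#'   available) and logical columns `effective_absolute` and/or
#'   `effective_relative` according to `mode`.
#' @export
effective_constraints <- function(ordering, mode = c("both", "absolute", "relative")) {
  mode <- match.arg(mode)
  if (inherits(ordering, "cv_ordering")) {
    tbl <- ordering$ordering[c("rank", "id", "value")]
  } else if (is.numeric(ordering)) {
    tbl <- tibble::tibble(rank = seq_along(ordering), value = as.double(ordering))
  } else {
    abort_input("`ordering` must be a cv_ordering or a numeric value sequence.")
  }
  v1 <- max(tbl$value, 0)
  if (mode %in% c("both", "absolute")) tbl$effective_absolute <- tbl$value >= 1
  if (mode %in% c("both", "relative")) tbl$effective_relative <- tbl$value > 0.01 * v1
  tbl
}
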