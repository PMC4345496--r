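# The approximate solution set.  Near a parameter set k* that satisfies
# the constraints, the set of parameters that satisfy them to within eps
# is, to leading order, an ellipsoidal cylinder: in the rotated
# coordinates lambda = W (k - k*) (W orthogonal, rows = right singular
# directions of the constraint matrix) the constrained coordinates must
# satisfy sum_i (sigma_i lambda_i / eps)^2 < 1 while the remaining s - m
# directions are unconstrained.  The semi-axis along direction i is
# eps / sigma_i: the smaller the singular value, the longer (sloppier)
# the axis.

#' Ellipsoid model of the approximate solution set
#'
#' @param x Constraint matrix (tibble or numeric matrix) of full row rank
#'   with `m <= s`.
#' @param eps Constraint-violation tolerance `eps > 0` defining the set
#'   `{k : ||C(k) - C(k*)|| < eps}` that the ellipsoid approximates.
#' @param k_star Reference parameter vector (length s, logged-parameter
#'   axis); defaults to the origin.
#' @param config A [cv_config()] list.
#' @return An object of class `cv_ellipsoid`: list with `eps`, `m`, `s`,
#'   `sigma` (positive singular values), `W` (s x s orthogonal matrix,
#'   rows are the rotated coordinate directions; the first m rows are
#'   constrained), `semi_axes` (`eps / sigma_i`), `k_star`, and
#'   `membership`, a predicate `function(k)` returning `TRUE` inside the
#'   set.
#' @export
#' @examples
#' em <- ellipsoid_model(diag(c(2, 1)), eps = 0.1)
#' em$semi_axes                  # 0.05 0.1
#' em$membership(c(0, 0))        # TRUE: k* is always a member
ellipsoid_model <- function(x, eps, k_star = NULL, config = cv_config()) {
  if (!is.numeric(eps) || length(eps) != 1 || eps <= 0) {
    abort_input("`eps` must be a single positive number.")
  }
  M <- cm_resolve(x)
  m <- nrow(M)
  s <- ncol(M)
  if (m > s) abort_input("Ellipsoid model requires m <= s.")
  sv <- svd(M, nu = 0, nv = s)
  pos <- sv$d > config$spectral_tol * max(sv$d, 0)
  if (sum(pos) < m) {
    abort_rank("Constraint matrix is rank deficient; the ellipsoid model assumes maximal rank.")
  }
  sigma <- sv$d
  V <- sv$v # s x s orthogonal (columns)
  W <- t(V) # rows are the rotated directions
  if (is.null(k_star)) k_star <- rep(0, s)
  if (length(k_star) != s) abort_input("`k_star` must have length s.")
  k_star <- as.double(k_star)

  membership <- function(k) {
    k <- as.double(k)
    if (length(k) != s) abort_input("`k` must have length s.")
    lambda <- drop(W %*% (k - k_star))
    sum((sigma * lambda[seq_len(m)] / eps)^2) < 1
  }

  structure(
    list(
      eps = eps, m = m, s = s,
      sigma = sigma,
      W = W,
      semi_axes = eps / sigma,
      unconstrained = if (m < s) seq.int(m + 1, s) else integer(0),
      k_star = k_star,
      params = colnames(M),
      membership = membership
    ),
    class = "cv_ellipsoid"
  )
}

#' @export
print.cv_ellipsoid <- function(x, ...) {
  cat("<cv_ellipsoid> eps = ", format(x$eps), ", m = ", x$m, ", s = ", x$s, "\n", sep = "")
  cat("  semi-axes eps/sigma_i: ", paste(signif(x$semi_axes, 4), collapse = ", "), "\n", sep = "")
  cat("  unconstrained directions: ", length(x$unconstrained), "\n", sep = "")
  invisible(x)
}

#' Validate the ellipsoid model against a nonlinear constraint map
#'
#' Samples parameter points around `k*` at the scale of the ellipsoid and
#' compares the exact approximate-solution indicator
#' `||C(k) - C(k*)|| <= eps` with the ellipsoid membership predicate.
#' As `eps` decreases, the higher-order terms of `C` become negligible at
#' the scale of the set and the agreement fraction tends to 1.
#'
#' @param C A function mapping a parameter vector (length s) to the
#'   vector of se-normalized constraint values.
#' @param k_star Reference parameter vector at which to linearize.
#' @param eps_list Numeric vector of positive tolerances to test.
#' @param n_samples Number of sampled points per tolerance.
#' @param seed Integer seed for the sampler.
#' @param M Optional constraint matrix (Jacobian of `C` at `k_star`); when
#'   `NULL` it is computed by central finite differences with step
#'   `1e-6`.
#' @param config A [cv_config()] list.
#' @return A tibble with columns `eps`, `agreement` (fraction of sampled
#'   points on which the two indicators agree) and `n`.
#' @export
validate_ellipsoid <- function(C, k_star, eps_list, n_samples = 20000,
                               seed = 1, M = NULL, config = cv_config()) {
  if (any(!is.finite(eps_list)) || any(eps_list <= 0)) {
    abort_input("`eps_list` must contain positive numbers.")
  }
  k_star <- as.double(k_star)
  s <- length(k_star)
  C0 <- as.double(C(k_star))
  m <- length(C0)
  if (is.null(M)) {
    h <- 1e-6
    M <- matrix(0, m, s)
    for (l in seq_len(s)) {
      e <- rep(0, s); e[l] <- h
      M[, l] <- (as.double(C(k_star + e)) - as.double(C(k_star - e))) / (2 * h)
    }
  } else {
    M <- cm_resolve(M)
  }
  out <- vector("list", length(eps_list))
  for (i in seq_along(eps_list)) {
    eps <- eps_list[i]
    em <- ellipsoid_model(M, eps, k_star = k_star, config = config)
    set.seed(seed)
    # sample lambda coordinates at twice the ellipsoid scale so both the
    # interior and the exterior are represented
    lam <- matrix(0, n_samples, s)
    for (j in seq_len(m)) {
      lam[, j] <- stats::runif(n_samples, -2 * eps / em$sigma[j], 2 * eps / em$sigma[j])
    }
    K <- t(em$W) %*% t(lam) + k_star # s x n
    pred <- colSums((em$sigma[seq_len(m)] * t(lam[, seq_len(m), drop = FALSE]) / eps)^2) < 1
    exact <- apply(K, 2, function(k) sqrt(sum((as.double(C(k)) - C0)^2)) <= eps)
    out[[i]] <- tibble::tibble(eps = eps, agreement = mean(pred == exact), n = n_samples)
  }
  dplyr::bind_rows(out)
}
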