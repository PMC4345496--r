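# Synthetic sloppy-constraint ensembles.  Large biochemical models share
# a spectral signature: the map from (logged) parameters to the solution
# of interest has rapidly decaying singular values mu_1 >= ... >= mu_s.
# Any constraint that acts through the solution then has a linearization
# c_i = sum_j mu_j gamma_ij w_j, where the w_j are the rows of an
# orthogonal matrix and the gamma_i are O(1)-norm coefficient vectors.
# The generator below draws such ensembles and lets the decay predictions
# (ordered values bounded by K mu_i; a large fraction of small-norm rows)
# be tested directly.

#' Generate a synthetic sloppy constraint ensemble
#'
#' Draws `W` as the orthogonalization of a seeded random Gaussian matrix,
#' sets geometric decay factors `mu_j = rho^(j-1)`, draws coefficient
#' vectors `gamma_i` with iid `N(0, 1/s)` entries (so their norms
#' concentrate near 1), and forms the constraint rows
#' `c_i = sum_j mu_j gamma_ij w_j`.
#'
#' @param s Parameter-space dimension.
#' @param m Number of constraints.
#' @param rho Geometric decay ratio in `(0, 1]`.
#' @param seed Integer seed; the ensemble is fully reproducible from it.
#' @param gamma Optional m x s coefficient matrix overriding the random
#'   draw (used e.g. to build exactly orthonormal coefficient sets).
#' @return An object of class `cv_ensemble`: list with `s`, `m`, `rho`,
#'   `mu` (decay factors), `W` (orthogonal s x s, rows `w_j`), `gamma`,
#'   `K = max_i ||gamma_i||`, `seed`, and `matrix`, the generated
#'   constraint-matrix tibble.
#' @export
#' @examples
#' en <- sloppy_ensemble(s = 10, m = 8, rho = 0.5, seed = 1)
#' ord <- order_constraints(en$matrix)
#' all(ord$values <= en$K * en$mu[seq_len(en$m)] + 1e-12)
sloppy_ensemble <- function(s, m, rho, seed = 1, gamma = NULL) {
  if (s < 1 || m < 1) abort_input("`s` and `m` must be positive integers.")
  if (!is.numeric(rho) || rho <= 0 || rho > 1) {
    abort_input("`rho` must be in (0, 1].")
  }
  set.seed(seed)
  A <- matrix(stats::rnorm(s * s), s, s)
  qrA <- qr(A)
  W <- qr.Q(qrA)
  # fix signs so the draw is unambiguous across LAPACK builds
  signs <- sign(diag(qr.R(qrA)))
  signs[signs == 0] <- 1
  W <- t(W * rep(signs, each = s)) # rows w_j
  mu <- rho^(seq_len(s) - 1)
  if (is.null(gamma)) {
    gamma <- matrix(stats::rnorm(m * s, sd = 1 / sqrt(s)), m, s)
  } else {
    gamma <- as.matrix(gamma)
    if (!all(dim(gamma) == c(m, s))) abort_input("`gamma` must be m x s.")
  }
  Crows <- gamma %*% (mu * W) # c_i = sum_j mu_j gamma_ij w_j
  structure(
    list(
      s = s, m = m, rho = rho, mu = mu, W = W, gamma = gamma,
      K = max(row_norms(gamma)),
      seed = seed,
      matrix = as_constraint_tbl(Crows, ids = paste0("e", seq_len(m)))
    ),
    class = "cv_ensemble"
  )
}

#' @export
print.cv_ensemble <- function(x, ...) {
  cat("<cv_ensemble> s = ", x$s, ", m = ", x$m, ", rho = ", x$rho,
      ", seed = ", x$seed, "\n", sep = "")
  cat("  K = max ||gamma_i|| = ", format(x$K), "\n", sep = "")
  invisible(x)
}

#' Fraction of small-norm constraints in an ensemble
#'
#' Computes the fraction of ensemble rows whose norm falls below
#' `frac * max norm`, and compares it against a Monte-Carlo reference
#' distribution of the same statistic under the generator's own model at
#' the same `(s, m, rho)`.  Row norms do not depend on the orthogonal
#' matrix `W`, so the reference only redraws the coefficient vectors.
#'
#' @param ensemble A `cv_ensemble` from [sloppy_ensemble()].
#' @param frac Screening fraction (default 0.1, the 10%-of-max rule).
#' @param n_mc Number of Monte-Carlo reference draws.
#' @param seed Seed for the reference draws.
#' @return A list with `empirical` (the ensemble's own fraction),
#'   `reference_mean`, `reference_se` (sampling standard error of the
#'   reference mean), `difference` (|empirical - reference_mean|) and
#'   `n_mc`.
#' @export
small_norm_fraction <- function(ensemble, frac = 0.1, n_mc = 10000, seed = 1) {
  if (!inherits(ensemble, "cv_ensemble")) {
    abort_input("`ensemble` must be a cv_ensemble.")
  }
  if (frac < 0) abort_input("`frac` must be non-negative.")
  norms <- row_norms(cm_matrix(ensemble$matrix))
  empirical <- mean(norms < frac * max(norms))

  m <- ensemble$m
  s <- ensemble$s
  mu2 <- ensemble$mu^2
  set.seed(seed)
  fractions <- numeric(n_mc)
  chunk <- 500L
  done <- 0L
  while (done < n_mc) {
    nb <- min(chunk, n_mc - done)
    G2 <- matrix(stats::rnorm(nb * m * s, sd = 1 / sqrt(s))^2, nb * m, s)
    rn <- sqrt(drop(G2 %*% mu2))
    rn <- matrix(rn, nb, m, byrow = TRUE)
    fractions[done + seq_len(nb)] <-
      rowMeans(rn < frac * apply(rn, 1, max))
    done <- done + nb
  }
  ref_mean <- mean(fractions)
  ref_se <- stats::sd(fractions) / sqrt(n_mc)
  list(
    empirical = empirical,
    reference_mean = ref_mean,
    reference_se = ref_se,
    reference_sd = stats::sd(fractions),
    difference = abs(empirical - ref_mean),
    n_mc = n_mc
  )
}

#' Log-linear decay profile of an ordered value sequence
#'
#' Ordered constraint values of sloppy models decay approximately
#' geometrically; this fits `log(v_i) ~ i` by least squares over the
#' strictly positive values and reports the slope (per-rank log decay)
#' with its confidence interval.  Diagnostic only.
#'
#' @param values Non-increasing numeric vector of ordered constraint
#'   values (zeros and non-positive entries are excluded from the fit).
#' @param conf_level Confidence level for the slope interval.
#' @return A list of class `cv_decay` with `slope`, `intercept`,
#'   `conf_low`, `conf_high`, `residual_sd`, `n_used` and the underlying
#'   `lm` fit.
#' @export
#' @examples
#' decay_profile(2^-(1:10))$slope   # -log(2)
decay_profile <- function(values, conf_level = 0.95) {
  values <- as.double(values)
  keep <- is.finite(values) & values > 0
  if (sum(keep) < 2) abort_input("Need at least two positive values to fit a decay profile.")
  d <- data.frame(rank = seq_along(values)[keep], logv = log(values[keep]))
  fit <- stats::lm(logv ~ rank, data = d)
  # exactly geometric inputs give a perfect fit; the lm machinery warns
  ci <- suppressWarnings(stats::confint(fit, "rank", level = conf_level))
  smry <- suppressWarnings(summary(fit))
  structure(
    list(
      slope = unname(stats::coef(fit)["rank"]),
      intercept = unname(stats::coef(fit)["(Intercept)"]),
      conf_low = ci[1], conf_high = ci[2],
      residual_sd = smry$sigma,
      n_used = sum(keep),
      fit = fit
    ),
    class = "cv_decay"
  )
}

#' @export
print.cv_decay <- function(x, ...) {
  cat("<cv_decay> slope = ", format(x$slope),
      " [", format(x$conf_low), ", ", format(x$conf_high), "]",
      ", ratio per rank = ", format(exp(x$slope)), "\n", sep = "")
  invisible(x)
}
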