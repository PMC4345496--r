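# Shared helpers: tiny analytic models and independent oracles.

# Random m x s constraint matrix with N(0,1) entries.
rand_cm <- function(seed, m, s) {
  set.seed(seed)
  matrix(rnorm(m * s), m, s)
}

# Independent least-squares oracle for the constraint value: residual
# norm of the regression of c on the rows (via base QR, a different code
# path from the package's truncated SVD).
ls_residual_norm <- function(c_vec, rows) {
  if (is.null(rows) || nrow(rows) == 0) return(sqrt(sum(c_vec^2)))
  fit <- lm.fit(t(rows), c_vec)
  sqrt(sum(fit$residuals^2))
}

# Brute-force ordering oracle: enumerate all m! permutations, compute
# each value sequence by sequential Gram-Schmidt, return the
# lexicographically maximal sequence (with tolerance).
brute_force_ordering <- function(M, tol = 1e-9) {
  m <- nrow(M)
  perms <- gtools_permutations(m)
  best <- NULL
  for (p in seq_len(nrow(perms))) {
    perm <- perms[p, ]
    vals <- numeric(m)
    basis <- matrix(0, 0, ncol(M))
    for (i in seq_len(m)) {
      r <- M[perm[i], ]
      if (nrow(basis) > 0) r <- r - drop(crossprod(basis, basis %*% r))
      v <- sqrt(sum(r^2))
      vals[i] <- v
      if (v > tol * max(sqrt(rowSums(M^2)))) basis <- rbind(basis, r / v)
    }
    if (is.null(best) || lex_greater(vals, best, tol)) best <- vals
  }
  best
}

lex_greater <- function(a, b, tol) {
  for (i in seq_along(a)) {
    if (a[i] > b[i] + tol) return(TRUE)
    if (a[i] < b[i] - tol) return(FALSE)
  }
  FALSE
}

# All permutations of 1..n (no extra packages).
gtools_permutations <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- gtools_permutations(n - 1)
  out <- matrix(0L, 0, n)
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub), n - 1)))
  }
  unname(out)
}

# One-parameter linear decay model dx/dt = -k x: closed forms
# x(t) = x0 exp(-k t), dx/dlog k = -k t x0 exp(-k t).
linear_decay_model <- function(k = 0.5, x0 = 1) {
  ps <- parameter_space(c(k = k))
  model <- ode_model(
    name = "lindecay",
    rhs = function(t, x, kk, u) -kk[["k"]] * x[1],
    state_names = "x", params = ps, time_unit = "h",
    nominal_period = 1, default_x0 = x0
  )
  list(
    model = model,
    variant = ge_variant(model, "decay", "transient", x0 = x0, horizon = 10)
  )
}

# Two-variable toy with a pure output-scaling parameter: k3 scales x2
# linearly (x2 does not feed back), so ratio features of x2 are
# invariant to k3 and its amplitude gradient equals the amplitude.
output_scaling_toy <- function() {
  ps <- parameter_space(c(k1 = 1, k2 = 0.2, k3 = 2, k4 = 0.2))
  model <- ode_model(
    name = "outscale",
    rhs = function(t, x, k, u) {
      c(
        k[["k1"]] * u * (1 + sin(t / 3)) - k[["k2"]] * x[1],
        k[["k3"]] * x[1] - k[["k4"]] * x[2]
      )
    },
    state_names = c("x1", "x2"), params = ps, time_unit = "h",
    nominal_period = 2 * pi * 3, default_x0 = c(0, 0)
  )
  list(
    model = model,
    variant = ge_variant(model, "toy", "transient",
                         schedule = input_schedule(NULL, default_level = 1),
                         x0 = c(0, 0), horizon = 60)
  )
}

# Fast transient-only study on the goodwin3 fixture (no entrained or
# free-running constraints), for pipeline-level tests.
fast_transient_study <- function(seed = 1, config = cv_config()) {
  fx <- goodwin3_fixture()
  cat0 <- tibble::tribble(
    ~id, ~kind, ~variant, ~j, ~t, ~delta, ~n1, ~n2,
    "lev_t20", "level", "wt_transient", 1, 20, NA, NA, NA,
    "lev_t60", "level", "wt_transient", 1, 60, NA, NA, NA,
    "pkt1", "peak_time", "wt_transient", 1, NA, NA, 1, NA,
    "pkl1", "peak_level", "wt_transient", 1, NA, NA, 1, NA,
    "pkr21", "peak_ratio", "wt_transient", 1, NA, NA, 1, 2,
    "lev_ko", "level", "ko_k3", 2, 10, NA, NA, NA
  )
  targets <- numeric(nrow(cat0))
  for (vid in unique(cat0$variant)) {
    idx <- which(cat0$variant == vid)
    reqs <- constraintvalue:::catalogue_requests(cat0[idx, ])
    targets[idx] <- constraintvalue:::variant_features(
      fx$variants[[vid]], fx$model$params$reference, reqs, config
    )
  }
  cat0$target <- targets
  set.seed(seed)
  cat0$se <- pmax(abs(targets), 0.01) * 10^runif(nrow(cat0), -2, -1)
  constraint_study(fx$model, fx$variants, cat0, seed = seed)
}
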