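# Built-in fixture models.
#
# goodwin3 -- a three-variable negative-feedback oscillator (mRNA ->
# protein -> repressor closing the loop through a fixed Hill
# nonlinearity).  Every kinetic term is proportional to exactly one rate
# parameter, so exact time-rescaling identities hold: multiplying all six
# rates by lambda speeds time up by lambda and halves the period when
# rates are doubled.  The Hill exponent is fixed (not perturbable),
# mirroring model parameters whose values were never fitted.  Stands in
# for circadian-clock models: free-running, light-entrained, and
# knockout variants.
#
# pulsefb2 -- a driven activation / negative-feedback cascade producing a
# damped transient oscillation under constant input (monotonically
# decaying peak levels) and pulse-triggered responses under repeated
# input pulses.  Stands in for signalling transients whose constraints
# are peak levels, peak times and peak-level ratios.  Time unit minutes.

#' The goodwin3 fixture: negative-feedback oscillator with variants
#'
#' Three states (mRNA `x1`, protein `x2`, repressor `x3`), six rate
#' parameters each appearing in exactly one term, and a fixed Hill
#' exponent `nh = 10`:
#' `dx1 = k1 (1 + 0.3 u) / (1 + x3^nh) - k2 x1`,
#' `dx2 = k3 x1 - k4 x2`, `dx3 = k5 x2 - k6 x3`.
#' At the reference rates the free-running period is about 39.7 h.
#'
#' @return A list with `model` (the [ode_model()]) and `variants`, a
#'   named list of [ge_variant()]s: `wt_free` (free-running periodic),
#'   `wt_entrained` (square-wave light, 20 h on / 20 h off, forcing
#'   period 40 h), `wt_transient` (off-attractor transient used for
#'   peak-based constraints) and `ko_k3` (translation knockout; the
#'   downstream variables decay to zero).
#' @export
goodwin3_fixture <- function() {
  rhs <- function(t, x, k, u) {
    c(
      k[["k1"]] * (1 + 0.3 * u) / (1 + x[3]^k[["nh"]]) - k[["k2"]] * x[1],
      k[["k3"]] * x[1] - k[["k4"]] * x[2],
      k[["k5"]] * x[2] - k[["k6"]] * x[3]
    )
  }
  ps <- parameter_space(
    c(k1 = 1, k2 = 0.1, k3 = 1, k4 = 0.1, k5 = 1, k6 = 0.1, nh = 10),
    fixed = "nh"
  )
  model <- ode_model(
    name = "goodwin3", rhs = rhs,
    state_names = c("x1", "x2", "x3"),
    params = ps, time_unit = "h",
    nominal_period = 40,
    default_x0 = c(0.2, 0.2, 2)
  )
  light <- input_schedule(
    data.frame(start = 0, end = 20, level = 1),
    period = 40, default_level = 0
  )
  variants <- list(
    wt_free = ge_variant(model, "wt_free", "periodic"),
    wt_entrained = ge_variant(model, "wt_entrained", "periodic", schedule = light),
    wt_transient = ge_variant(model, "wt_transient", "transient",
                              x0 = c(0.05, 0.05, 0.5), horizon = 200),
    ko_k3 = ge_variant(model, "ko_k3", "transient",
                       knockouts = "k3",
                       x0 = c(1, 1, 1), horizon = 300)
  )
  list(model = model, variants = variants)
}

#' The pulsefb2 fixture: driven damped-feedback transient with variants
#'
#' Three states driven by an external input `u(t)`:
#' `dx1 = ka u / (1 + x3^hh) - kd1 x1`, `dx2 = kf x1 - kd2 x2`,
#' `dx3 = kg x2 - kd3 x3`, Hill exponent `hh = 6` fixed.  Under constant
#' input from `x0 = 0` the response is a damped oscillation with at
#' least five peaks whose levels decrease monotonically; under repeated
#' short pulses each pulse triggers a response peak.  Time unit minutes.
#'
#' @return A list with `model` and `variants`: `const` (constant input,
#'   the main transient), `zero` (zero input: flat trajectory),
#'   `pulse60`, `pulse100`, `pulse200` (5-min input pulses repeated
#'   every 60/100/200 min).
#' @export
pulsefb2_fixture <- function() {
  rhs <- function(t, x, k, u) {
    c(
      k[["ka"]] * u / (1 + x[3]^k[["hh"]]) - k[["kd1"]] * x[1],
      k[["kf"]] * x[1] - k[["kd2"]] * x[2],
      k[["kg"]] * x[2] - k[["kd3"]] * x[3]
    )
  }
  ps <- parameter_space(
    c(ka = 1, kd1 = 0.15, kf = 1, kd2 = 0.15, kg = 1, kd3 = 0.15, hh = 6),
    fixed = "hh"
  )
  model <- ode_model(
    name = "pulsefb2", rhs = rhs,
    state_names = c("x1", "x2", "x3"),
    params = ps, time_unit = "min",
    nominal_period = 27,
    default_x0 = c(0, 0, 0)
  )
  pulse <- function(interval) {
    input_schedule(data.frame(start = 0, end = 5, level = 1),
                   period = interval, default_level = 0)
  }
  const <- input_schedule(NULL, default_level = 1)
  variants <- list(
    const = ge_variant(model, "const", "transient", schedule = const,
                       x0 = c(0, 0, 0), horizon = 400),
    zero = ge_variant(model, "zero", "transient",
                      schedule = input_schedule(NULL, default_level = 0),
                      x0 = c(0, 0, 0), horizon = 400),
    pulse60 = ge_variant(model, "pulse60", "transient", schedule = pulse(60),
                         x0 = c(0, 0, 0), horizon = 600),
    pulse100 = ge_variant(model, "pulse100", "transient", schedule = pulse(100),
                          x0 = c(0, 0, 0), horizon = 600),
    pulse200 = ge_variant(model, "pulse200", "transient", schedule = pulse(200),
                          x0 = c(0, 0, 0), horizon = 600)
  )
  list(model = model, variants = variants)
}

#' Fixture model registry
#'
#' @param name Fixture name: `"goodwin3"` or `"pulsefb2"`.
#' @return The fixture list (`model` + `variants`).
#' @export
fixture_registry <- function(name) {
  switch(name,
    goodwin3 = goodwin3_fixture(),
    pulsefb2 = pulsefb2_fixture(),
    abort_input(paste0("Unknown fixture model: '", name, "'."))
  )
}
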