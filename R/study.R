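# Synthetic fixture study: a full constraint catalogue over the goodwin3
# variants, with targets set to the model's own feature values at the
# reference parameters and synthetic standard errors.  This emulates the
# structure of a real calibration data set (levels under entrainment,
# free-running period, peak-shape features, knockout levels) at desk
# scale, so the whole pipeline can be exercised end to end.

#' Build the synthetic fixture study
#'
#' Constructs a [constraint_study()] on the goodwin3 fixture whose
#' catalogue spans every constraint kind: levels of the entrained cycle
#' at four times of day, the free-running period, amplitude and fall
#' ratio of the free-running cycle, peak time / peak levels / peak
#' ratios of the off-attractor transient, and two levels of the
#' knockout transient (masked at the knocked-out rate).  Targets are the
#' model's own feature values at the reference parameters; standard
#' errors are drawn log-uniformly between 1% and 10% of the target scale.
#'
#' @param seed Integer seed (drives the synthetic standard errors).
#' @param duplicate_pair If `TRUE`, appends a structurally identical copy
#'   of one level constraint (same variant, variable, time, se) under a
#'   new id, reproducing the near-identical-constraint signature that
#'   lands at the bottom of the ordering with value ~ 0.
#' @param config A [cv_config()] list used to evaluate the targets.
#' @return A `cv_study` whose catalogue has columns `id`, `kind`,
#'   `variant`, `j`, `t`, `delta`, `n1`, `n2`, `target`, `se`.
#' @export
make_fixture_study <- function(seed = 1, duplicate_pair = FALSE,
                               config = cv_config()) {
  fx <- goodwin3_fixture()
  cat0 <- tibble::tribble(
    ~id, ~kind, ~variant, ~j, ~t, ~delta, ~n1, ~n2,
    "lev_e04", "level", "wt_entrained", 1, 4, NA, NA, NA,
    "lev_e12", "level", "wt_entrained", 1, 12, NA, NA, NA,
    "lev_e24", "level", "wt_entrained", 1, 24, NA, NA, NA,
    "lev_e32", "level", "wt_entrained", 1, 32, NA, NA, NA,
    "per_free", "period", "wt_free", NA, NA, NA, NA, NA,
    "amp_free", "amplitude", "wt_free", 1, NA, NA, NA, NA,
    "fall_free", "fall_ratio", "wt_free", 1, NA, 2, 1, NA,
    "pkt_tr1", "peak_time", "wt_transient", 1, NA, NA, 1, NA,
    "pkl_tr1", "peak_level", "wt_transient", 1, NA, NA, 1, NA,
    "pkl_tr2", "peak_level", "wt_transient", 1, NA, NA, 2, NA,
    "pkr_tr21", "peak_ratio", "wt_transient", 1, NA, NA, 1, 2,
    "pkr_tr31", "peak_ratio", "wt_transient", 1, NA, NA, 1, 3,
    "lev_ko05", "level", "ko_k3", 2, 5, NA, NA, NA,
    "lev_ko15", "level", "ko_k3", 2, 15, NA, NA, NA
  )
  if (duplicate_pair) {
    dup <- cat0[cat0$id == "lev_e12", ]
    dup$id <- "lev_e12_dup"
    cat0 <- dplyr::bind_rows(cat0, dup)
  }
  # targets: the model's own feature values at the reference parameters
  targets <- numeric(nrow(cat0))
  for (vid in unique(cat0$variant)) {
    idx <- which(cat0$variant == vid)
    reqs <- catalogue_requests(cat0[idx, ])
    targets[idx] <- variant_features(fx$variants[[vid]],
                                     fx$model$params$reference, reqs, config)
  }
  cat0$target <- targets
  set.seed(seed)
  scale <- pmax(abs(targets), 0.01)
  cat0$se <- scale * 10^stats::runif(nrow(cat0), -2, -1)
  if (duplicate_pair) {
    cat0$se[cat0$id == "lev_e12_dup"] <- cat0$se[cat0$id == "lev_e12"]
  }
  constraint_study(fx$model, fx$variants, cat0, seed = seed)
}
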