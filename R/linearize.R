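# From constraint catalogue to constraint matrix.
#
# A catalogue row describes one constraint: its kind (level, period,
# peak_time, amplitude, fall_ratio, peak_level, peak_ratio), the variant
# it is measured on, its feature parameters, the data-derived target and
# its standard error.  Linearization computes the raw feature gradient
# in logged parameters, divides elementwise by the standard error, and
# zeroes the masked coordinates (knockouts, fixed parameters, declared
# dead sub-networks), yielding one row of the constraint matrix.

catalogue_cols <- c("id", "kind", "variant", "j", "t", "delta", "n1", "n2",
                    "target", "se")

#' Assemble a constraint study
#'
#' Bundles a model, its GE-variants and a constraint catalogue into the
#' object the linearization pipeline consumes.
#'
#' @param model A [ode_model()].
#' @param variants Named list of [ge_variant()]s (names must match the
#'   catalogue's `variant` column).
#' @param catalogue Constraint catalogue tibble with columns `id`,
#'   `kind`, `variant`, `j`, `t`, `delta`, `n1`, `n2`, `target`, `se`
#'   (missing feature parameters may be `NA`).
#' @param seed Seed recorded with the study.
#' @return A list of class `cv_study`.
#' @export
constraint_study <- function(model, variants, catalogue, seed = NA_integer_) {
  if (!inherits(model, "cv_model")) abort_input("`model` must be a cv_model.")
  if (is.null(names(variants)) || !all(vapply(variants, inherits, logical(1), "cv_variant"))) {
    abort_input("`variants` must be a named list of cv_variant objects.")
  }
  catalogue <- tibble::as_tibble(catalogue)
  for (col in setdiff(catalogue_cols, names(catalogue))) {
    catalogue[[col]] <- NA
  }
  catalogue <- catalogue[catalogue_cols]
  if (anyDuplicated(catalogue$id)) abort_input("Catalogue ids must be unique.")
  bad <- setdiff(unique(catalogue$variant), names(variants))
  if (length(bad) > 0) {
    abort_input(paste0("Catalogue references unknown variant(s): ", paste(bad, collapse = ", ")))
  }
  if (any(!is.finite(catalogue$se) | catalogue$se <= 0)) {
    abort_input("Every catalogue entry needs a positive standard error `se`.")
  }
  structure(
    list(model = model, variants = variants, catalogue = catalogue, seed = seed),
    class = "cv_study"
  )
}

#' @export
print.cv_study <- function(x, ...) {
  cat("<cv_study> model '", x$model$name, "', ", length(x$variants),
      " variants, ", nrow(x$catalogue), " constraints\n", sep = "")
  print(dplyr::count(x$catalogue, .data$variant, .data$kind))
  invisible(x)
}

catalogue_requests <- function(rows) {
  purrr::map(seq_len(nrow(rows)), function(i) {
    r <- rows[i, ]
    feature_request(r$id, r$kind, j = r$j, t = r$t, delta = r$delta,
                    n1 = r$n1, n2 = r$n2)
  })
}

#' Linearize a constraint catalogue
#'
#' Computes the se-normalized linearized constraint for every catalogue
#' row and assembles the constraint matrix.  Rows of the same variant
#' share the perturbed model solutions, so the cost is about
#' `2 * n_perturbable + 1` integrations (or orbit searches) per variant,
#' not per constraint.
#'
#' @param study A [constraint_study()].
#' @param catalogue Optional subset of the study's catalogue (defaults to
#'   all rows).
#' @param params Named parameter vector at which to linearize (defaults
#'   to the model's reference values).
#' @param config A [cv_config()] list.
#' @return A constraint-matrix tibble: columns `id`, `variant`, `kind`,
#'   `target`, `se`, then one column per (logged) parameter holding the
#'   se-normalized gradient, with exact zeros at masked coordinates.
#'   The raw (unnormalized) gradients are attached as attribute
#'   `raw_gradients`; entrained period rows are flagged in attribute
#'   `entrained_period_ids`.
#' @export
linearize_constraints <- function(study, catalogue = NULL, params = NULL,
                                  config = cv_config()) {
  if (!inherits(study, "cv_study")) abort_input("`study` must be a cv_study.")
  if (is.null(catalogue)) catalogue <- study$catalogue
  catalogue <- tibble::as_tibble(catalogue)
  if (nrow(catalogue) == 0) abort_input("Empty catalogue.")
  if (any(!is.finite(catalogue$se) | catalogue$se <= 0)) {
    abort_input("Every catalogue entry needs a positive standard error `se`.")
  }
  pn <- study$model$params$names

  out <- vector("list", 0)
  raw_list <- list()
  entrained_ids <- character(0)
  for (vid in unique(catalogue$variant)) {
    rows <- catalogue[catalogue$variant == vid, ]
    variant <- study$variants[[vid]]
    if (is.null(variant)) abort_input(paste0("Unknown variant '", vid, "'."))
    fg <- feature_gradients(variant, params, catalogue_requests(rows), config)
    G <- fg$gradients # n_rows x s (already zero at non-perturbable)
    # exact zeros at masked coordinates
    G[, !fg$mask] <- 0
    if (variant$entrained) {
      entrained_ids <- c(entrained_ids, rows$id[rows$kind == "period"])
    }
    norm <- G / rows$se
    tbl <- dplyr::bind_cols(
      rows[c("id", "variant", "kind", "target", "se")],
      tibble::as_tibble(norm)
    )
    raw_list[[vid]] <- G
    out[[length(out) + 1]] <- tbl
  }
  res <- dplyr::bind_rows(out)
  # restore catalogue order
  res <- res[match(catalogue$id, res$id), ]
  raw <- do.call(rbind, raw_list)
  raw <- raw[match(catalogue$id, rownames(raw)), , drop = FALSE]
  attr(res, "raw_gradients") <- raw
  attr(res, "entrained_period_ids") <- entrained_ids
  res
}

#' Linearize a single constraint specification
#'
#' @param spec A one-row catalogue tibble (or named list coercible to
#'   one).
#' @inheritParams linearize_constraints
#' @return A one-row constraint-matrix tibble (see
#'   [linearize_constraints()]).
#' @export
linearize_constraint <- function(spec, study, params = NULL, config = cv_config()) {
  spec <- tibble::as_tibble(spec)
  if (nrow(spec) != 1) abort_input("`spec` must be a single catalogue row.")
  linearize_constraints(study, catalogue = spec, params = params, config = config)
}

#' Rank stability of a constraint ordering under parameter perturbation
#'
#' Repeats the full linearize-and-order pipeline at perturbed parameter
#' sets: each rate `k_j` receives additive Gaussian noise with standard
#' deviation `sd_frac * k_j` (redrawn if the result is non-positive),
#' the catalogue is re-linearized and re-ordered, and each constraint's
#' rank is recorded.  Reports the per-draw rank of every constraint and
#' the overlap of each draw's top 10 with the reference ordering's
#' top 10.
#'
#' @param study A [constraint_study()].
#' @param n_sets Number of perturbed parameter draws.
#' @param sd_frac Relative perturbation scale (default 0.05).
#' @param seed Integer seed.
#' @param config A [cv_config()] list.
#' @param top_n Size of the overlap set (default 10, capped at the
#'   catalogue size).
#' @return An object of class `cv_rank_stability`: list with `ranks` (a
#'   tibble `draw`, `id`, `rank`, `value`; draw 0 is the unperturbed
#'   reference), `top_overlap` (per perturbed draw, the fraction of the
#'   reference top-`top_n` that stays in the draw's top-`top_n`),
#'   `skipped` (draws dropped after integration failure), `sd_frac`,
#'   `seed`.
#' @export
rank_stability <- function(study, n_sets = 10, sd_frac = 0.05, seed = 1,
                           config = cv_config(), top_n = 10) {
  if (!inherits(study, "cv_study")) abort_input("`study` must be a cv_study.")
  top_n <- min(top_n, nrow(study$catalogue))
  ref <- study$model$params$reference
  set.seed(seed)

  run_one <- function(params, draw) {
    M <- linearize_constraints(study, params = params, config = config)
    ord <- order_constraints(M, config)
    tibble::tibble(draw = draw, id = ord$ordering$id,
                   rank = ord$ordering$rank, value = ord$ordering$value)
  }

  base_tbl <- run_one(ref, 0L)
  base_top <- base_tbl$id[base_tbl$rank <= top_n]

  draws <- list()
  skipped <- integer(0)
  for (d in seq_len(n_sets)) {
    p <- ref
    if (sd_frac > 0) {
      for (j in seq_along(p)) {
        repeat {
          val <- ref[j] + stats::rnorm(1, 0, sd_frac * ref[j])
          if (val > 0) break
        }
        p[j] <- val
      }
    }
    tbl <- tryCatch(
      run_one(p, d),
      cv_error = function(e) {
        warning(sprintf("rank_stability: draw %d skipped (%s)", d, conditionMessage(e)),
                call. = FALSE)
        NULL
      }
    )
    if (is.null(tbl)) skipped <- c(skipped, d) else draws[[length(draws) + 1]] <- tbl
  }
  ranks <- dplyr::bind_rows(c(list(base_tbl), draws))
  overlap <- ranks |>
    dplyr::filter(.data$draw > 0, .data$rank <= top_n) |>
    dplyr::group_by(.data$draw) |>
    dplyr::summarise(top_overlap = mean(.data$id %in% base_top), .groups = "drop")
  structure(
    list(
      ranks = ranks, top_overlap = overlap, base_top = base_top,
      skipped = skipped, n_sets = n_sets, sd_frac = sd_frac,
      seed = seed, top_n = top_n
    ),
    class = "cv_rank_stability"
  )
}

#' @export
print.cv_rank_stability <- function(x, ...) {
  cat("<cv_rank_stability> ", x$n_sets, " draws (", length(x$skipped),
      " skipped), sd_frac = ", x$sd_frac, "\n", sep = "")
  if (nrow(x$top_overlap) > 0) {
    cat("  mean top-", x$top_n, " overlap: ",
        format(mean(x$top_overlap$top_overlap)), "\n", sep = "")
  }
  invisible(x)
}
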