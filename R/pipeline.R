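# End-to-end pipeline: linearize -> screen -> order -> spectrum
# (-> design) with every artefact written to an output directory and
# every configuration value logged.

#' Run the full constraint-value pipeline
#'
#' Chains the stages on a study (catalogue of constraint specifications
#' plus model variants) or on a precomputed constraint matrix: (1)
#' linearize the catalogue, (2) screen rows by raw norm, (3) order the
#' kept rows by constraint value, (4) spectral report of the kept
#' matrix, (5, optional) design report for candidate constraints plus a
#' transition report for the best candidate.  Each stage failure aborts
#' with the stage name; all outputs and the full configuration are
#' written under `out_dir`.
#'
#' @param study A [constraint_study()], or `NULL` when `matrix` is
#'   given.
#' @param matrix A precomputed constraint-matrix tibble, or a path to a
#'   constraint-matrix CSV (pure linear-algebra workflow).
#' @param candidate_ids Catalogue/matrix ids treated as design
#'   candidates instead of applied constraints.
#' @param out_dir Output directory (created if missing).
#' @param screen_frac Norm-screen fraction (see [screen_norms()]).
#' @param config A [cv_config()] list.
#' @param seed Seed recorded in the run report.
#' @return A list of class `cv_pipeline` with the stage objects
#'   (`matrix`, `screen`, `ordering`, `spectrum`, `design`,
#'   `transition`) and `files`, the paths written.
#' @export
run_pipeline <- function(study = NULL, matrix = NULL, candidate_ids = character(),
                         out_dir = tempfile("cvrun"), screen_frac = 0.1,
                         config = cv_config(), seed = NA_integer_) {
  if (is.null(study) && is.null(matrix)) {
    abort_input("Provide a `study` or a `matrix`.")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      rlang::abort(paste0("Pipeline stage '", name, "' failed: ", conditionMessage(e)),
                   class = c("cv_pipeline_error", "cv_error"))
    })
  }

  M <- stage("linearize", {
    if (!is.null(matrix)) {
      if (is.character(matrix)) read_constraint_matrix(matrix) else matrix
    } else {
      linearize_constraints(study, config = config)
    }
  })
  if (!is.data.frame(M)) M <- as_constraint_tbl(M)
  files$matrix <- file.path(out_dir, "constraint_matrix.csv")
  write_constraint_matrix(M, files$matrix)

  is_cand <- M$id %in% candidate_ids
  applied <- M[!is_cand, , drop = FALSE]
  cands <- M[is_cand, , drop = FALSE]

  scr <- stage("screen", screen_norms(applied, frac = screen_frac))
  files$screen <- file.path(out_dir, "screen.json")
  jsonlite::write_json(
    list(frac = scr$frac, threshold = scr$threshold,
         n_kept = scr$n_kept, n_dropped = scr$n_dropped,
         dropped_ids = scr$dropped$id),
    files$screen, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )

  ord <- stage("order", order_constraints(scr$kept, config))
  files$ordering <- file.path(out_dir, "ordering.json")
  write_ordering_json(ord, files$ordering)

  spec <- stage("spectrum", constraint_spectrum(scr$kept, config))
  files$spectrum <- file.path(out_dir, "spectrum.json")
  jsonlite::write_json(
    list(singular_values = spec$singular_values, rank = spec$rank,
         condition = spec$condition, m = spec$m, s = spec$s),
    files$spectrum, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )

  design <- NULL
  transition <- NULL
  if (nrow(cands) > 0) {
    design <- stage("design", design_report(scr$kept, cands, config))
    files$design <- file.path(out_dir, "design_report.csv")
    readr::write_csv(design, files$design)
    best <- cands[cands$id == design$id[1], , drop = FALSE]
    transition <- stage("transition", transition_add(scr$kept, best, config))
    files$transition <- file.path(out_dir, "transition.json")
    jsonlite::write_json(
      list(candidate = design$id[1],
           sigma_before = transition$sigma_before,
           sigma_after = transition$sigma_after,
           value = transition$value,
           interlacing_ok = transition$interlacing_ok,
           new_smallest_ok = transition$new_smallest_ok,
           condition_ok = transition$condition_ok),
      files$transition, auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }

  files$report <- file.path(out_dir, "run_report.json")
  jsonlite::write_json(
    list(seed = seed, screen_frac = screen_frac,
         config = unclass(config),
         n_constraints = nrow(M), n_candidates = nrow(cands),
         model = if (!is.null(study)) study$model$name else NA),
    files$report, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )

  structure(
    list(matrix = M, screen = scr, ordering = ord, spectrum = spec,
         design = design, transition = transition, files = files,
         out_dir = out_dir),
    class = "cv_pipeline"
  )
}

#' @export
print.cv_pipeline <- function(x, ...) {
  cat("<cv_pipeline> ", nrow(x$matrix), " constraints -> ", x$out_dir, "\n", sep = "")
  cat("  kept after screen: ", x$screen$n_kept,
      "; top value: ", format(x$ordering$values[1]), "\n", sep = "")
  invisible(x)
}
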