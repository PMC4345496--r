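# Experimental-design ranking: given the constraints already applied,
# score each candidate experiment by the value of the constraint it would
# contribute.

#' Rank candidate constraints for experimental design
#'
#' For each candidate row, reports its constraint value against the
#' existing set, whether it would improve the condition number of the
#' constraint matrix (value above the smallest positive singular value),
#' its rank and value after re-ordering the union of existing set and
#' candidate (a candidate can move far up the ordering, so the union is
#' always re-ordered before judging it), and its value as a fraction of
#' the top ordered value.
#'
#' @param x Existing constraint matrix (tibble or numeric matrix).
#' @param candidates Candidate constraints: constraint-matrix tibble or
#'   numeric matrix, one row per candidate experiment.
#' @param config A [cv_config()] list.
#' @return A tibble of class `cv_design` sorted by decreasing value, with
#'   columns `id`, `norm`, `value` (against the existing set),
#'   `rank_after` and `value_after` (rank/value of the candidate in the
#'   re-ordered union), `frac_of_top` (`value_after / v_1` of the union
#'   ordering), `improves` and `margin` (from [improvement_verdict()]).
#' @export
#' @examples
#' M <- rbind(c(1, 0, 0), c(0, 1, 0))
#' cand <- as_constraint_tbl(rbind(new = c(0, 0, 2), dup = c(1, 0, 0)))
#' design_report(M, cand)
design_report <- function(x, candidates, config = cv_config()) {
  M <- cm_resolve(x)
  Cm <- cm_resolve(candidates, "candidates")
  if (ncol(Cm) != ncol(M)) {
    abort_input("Parameter-axis mismatch between candidates and existing matrix.")
  }
  if (!is.null(colnames(Cm)) && !is.null(colnames(M)) &&
      !identical(colnames(Cm), colnames(M))) {
    abort_input("Parameter-axis mismatch: candidate and matrix parameter names differ.")
  }
  ids <- rownames(Cm)
  if (is.null(ids)) ids <- paste0("cand", seq_len(nrow(Cm)))

  rows <- purrr::map(seq_len(nrow(Cm)), function(i) {
    ci <- Cm[i, ]
    verdict <- improvement_verdict(M, ci, config)
    union <- rbind(M, candidate = ci)
    ord <- order_constraints(union, config)
    pos <- which(ord$permutation == nrow(union))
    tibble::tibble(
      id = ids[i],
      norm = vec_norm(ci),
      value = verdict$value,
      rank_after = pos,
      value_after = ord$values[pos],
      frac_of_top = ord$values[pos] / ord$values[1],
      improves = verdict$improves,
      margin = verdict$margin
    )
  })
  out <- dplyr::arrange(dplyr::bind_rows(rows), dplyr::desc(.data$value))
  class(out) <- c("cv_design", class(out))
  out
}
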