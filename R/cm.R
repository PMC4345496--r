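# Constraint-matrix tibble dialect.
#
# A constraint matrix is an m x s array of se-normalized linearized
# constraints carried as a tibble: the reserved metadata columns
# (id, variant, kind, target, se -- all optional except id) come first,
# every remaining column is one logged-parameter axis.  All algebra
# functions also accept a plain numeric matrix.

cm_meta_cols <- c("id", "variant", "kind", "target", "se", "norm")

#' Parameter columns of a constraint-matrix tibble
#'
#' @param x A constraint-matrix tibble (metadata columns `id`, `variant`,
#'   `kind`, `target`, `se` plus one numeric column per logged parameter).
#' @return Character vector of parameter-axis column names.
#' @export
cm_params <- function(x) {
  if (!is.data.frame(x)) abort_input("`x` must be a constraint-matrix tibble.")
  setdiff(names(x), cm_meta_cols)
}

#' Extract the numeric matrix from a constraint-matrix tibble
#'
#' @inheritParams cm_params
#' @return An m x s numeric matrix; row names are constraint ids when an
#'   `id` column is present, column names are the parameter axis.
#' @export
cm_matrix <- function(x) {
  if (is.matrix(x)) {
    storage.mode(x) <- "double"
    return(x)
  }
  if (!is.data.frame(x)) {
    abort_input("Constraint matrix must be a tibble or a numeric matrix.")
  }
  pc <- cm_params(x)
  if (length(pc) == 0) abort_input("Constraint-matrix tibble has no parameter columns.")
  bad <- pc[!vapply(x[pc], is.numeric, logical(1))]
  if (length(bad) > 0) {
    abort_input(paste0("Non-numeric parameter columns: ", paste(bad, collapse = ", ")))
  }
  M <- as.matrix(x[pc])
  if (!is.null(x[["id"]])) rownames(M) <- as.character(x[["id"]])
  M
}

#' Build a constraint-matrix tibble from a numeric matrix
#'
#' @param M Numeric matrix, one row per linearized constraint.
#' @param ids Constraint identifiers (default `c1, c2, ...` or row names).
#' @param params Parameter-axis names (default `p1, p2, ...` or column
#'   names).
#' @return A constraint-matrix tibble with an `id` column.
#' @export
#' @examples
#' as_constraint_tbl(rbind(c(1, 0), c(1, 1)))
as_constraint_tbl <- function(M, ids = NULL, params = NULL) {
  M <- as.matrix(M)
  storage.mode(M) <- "double"
  if (is.null(ids)) {
    ids <- rownames(M)
    if (is.null(ids)) ids <- paste0("c", seq_len(nrow(M)))
  }
  if (is.null(params)) {
    params <- colnames(M)
    if (is.null(params)) params <- paste0("p", seq_len(ncol(M)))
  }
  if (length(ids) != nrow(M)) abort_input("`ids` length must equal nrow(M).")
  if (length(params) != ncol(M)) abort_input("`params` length must equal ncol(M).")
  colnames(M) <- params
  dplyr::bind_cols(tibble::tibble(id = as.character(ids)), tibble::as_tibble(M))
}

# Internal: coerce tibble/matrix to a validated numeric matrix and check
# all entries finite.
cm_resolve <- function(x, arg = "x") {
  M <- cm_matrix(x)
  if (nrow(M) == 0) abort_input(paste0("`", arg, "` has no constraint rows."))
  if (!all(is.finite(M))) abort_input(paste0("`", arg, "` contains non-finite entries."))
  M
}

# Internal: coerce a candidate constraint (numeric vector, 1-row tibble,
# or 1-row matrix) to a named numeric vector.
cm_resolve_row <- function(c_new, arg = "c_new") {
  if (is.data.frame(c_new) || (is.matrix(c_new) && nrow(c_new) == 1)) {
    M <- cm_matrix(c_new)
    if (nrow(M) != 1) abort_input(paste0("`", arg, "` must be a single constraint row."))
    v <- M[1, ]
  } else if (is.numeric(c_new)) {
    v <- as.double(c_new)
    names(v) <- names(c_new)
  } else {
    abort_input(paste0("`", arg, "` must be a numeric vector or a one-row constraint tibble."))
  }
  if (!all(is.finite(v))) abort_input(paste0("`", arg, "` contains non-finite entries."))
  v
}

# Internal: check a candidate row and an existing matrix live on the same
# parameter axis (same length; same names when both are named).
cm_check_axis <- function(v, M) {
  if (length(v) != ncol(M)) {
    abort_input(sprintf(
      "Parameter-axis mismatch: candidate has %d entries, matrix has %d columns.",
      length(v), ncol(M)
    ))
  }
  if (!is.null(names(v)) && !is.null(colnames(M)) &&
      !identical(names(v), colnames(M))) {
    abort_input("Parameter-axis mismatch: candidate and matrix parameter names differ.")
  }
  invisible(TRUE)
}

row_norms <- function(M) sqrt(rowSums(M^2))
vec_norm <- function(v) sqrt(sum(v^2))
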