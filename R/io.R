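# File formats.
#
# Constraint-matrix CSV: header "id,variant,kind,target,se,<param_1>,...",
# one row per constraint, numeric entries serialized with full
# (round-trip) precision so write -> read reproduces values bit-exactly.
# Constraint catalogues travel as CSV or JSON; ordering results and
# reports as JSON; trajectories as CSV with header "time,var_1,...".

#' Write a constraint matrix to CSV
#'
#' @param x Constraint-matrix tibble (or numeric matrix, converted with
#'   [as_constraint_tbl()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_constraint_matrix <- function(x, path) {
  if (!is.data.frame(x)) x <- as_constraint_tbl(x)
  # serialize doubles at 17 significant digits so read-back is bit-exact
  out <- dplyr::mutate(
    tibble::as_tibble(x),
    dplyr::across(dplyr::where(is.double), ~ formatC(.x, digits = 17, format = "g"))
  )
  readr::write_csv(out, path, quote = "none")
  invisible(path)
}

#' Read a constraint matrix from CSV
#'
#' @param path CSV file in the constraint-matrix dialect.
#' @return A constraint-matrix tibble.
#' @export
read_constraint_matrix <- function(path) {
  # read numerics as text and convert with base strtod (correctly rounded),
  # so write -> read reproduces doubles bit-exactly
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                       col_types = readr::cols(.default = readr::col_character()))
  num_cols <- setdiff(names(x), c("id", "variant", "kind"))
  for (col in num_cols) {
    v <- suppressWarnings(as.double(x[[col]]))
    if (any(is.na(v) & !is.na(x[[col]]))) {
      abort_input(paste0("Non-numeric entries in column '", col, "' of ", path, "."))
    }
    x[[col]] <- v
  }
  pc <- setdiff(names(x), cm_meta_cols)
  if (length(pc) == 0) {
    abort_input(paste0("No parameter columns found in ", path, "."))
  }
  if ("id" %in% names(x)) x$id <- as.character(x$id)
  x
}

#' Write / read a constraint catalogue
#'
#' CSV or JSON, chosen by the file extension.  Columns: `id`, `kind`,
#' `variant`, `j`, `t`, `delta`, `n1`, `n2`, `target`, `se`.
#'
#' @param catalogue Catalogue tibble.
#' @param path File path ending in `.csv` or `.json`.
#' @return `path` (write) or the catalogue tibble (read).
#' @export
write_catalogue <- function(catalogue, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(catalogue, path, auto_unbox = FALSE, digits = NA,
                         na = "null", pretty = TRUE)
  } else {
    readr::write_csv(tibble::as_tibble(catalogue), path)
  }
  invisible(path)
}

#' @rdname write_catalogue
#' @export
read_catalogue <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    x <- tibble::as_tibble(jsonlite::fromJSON(path))
  } else {
    x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  }
  miss <- setdiff(c("id", "kind", "variant", "target", "se"), names(x))
  if (length(miss) > 0) {
    abort_input(paste0("Catalogue is missing column(s): ", paste(miss, collapse = ", ")))
  }
  x$id <- as.character(x$id)
  x
}

#' Serialize an ordering result to JSON
#'
#' @param ordering A `cv_ordering` from [order_constraints()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ordering_json <- function(ordering, path) {
  if (!inherits(ordering, "cv_ordering")) abort_input("`ordering` must be a cv_ordering.")
  payload <- list(
    permutation = ordering$permutation,
    ids = ordering$ordering$id,
    values = ordering$values,
    ties = ordering$ties,
    m = ordering$m, s = ordering$s,
    config = ordering$config
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Export a trajectory to CSV
#'
#' Header `time,var_1,...,var_n`.
#'
#' @param traj A `cv_trajectory`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  if (!inherits(traj, "cv_trajectory")) abort_input("`traj` must be a cv_trajectory.")
  tbl <- tibble::as_tibble(traj$states)
  names(tbl) <- paste0("var_", seq_len(ncol(tbl)))
  tbl <- dplyr::bind_cols(tibble::tibble(time = traj$times), tbl)
  readr::write_csv(tbl, path)
  invisible(path)
}
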