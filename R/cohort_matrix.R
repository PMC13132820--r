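#' Construct a cohort data block
#'
#' A `cohort_matrix` is a numeric participant-by-feature matrix carrying
#' per-column metadata: the measurement kind (`binary`, `ordinal`,
#' `continuous`) and the treatment phase in which the feature was measured
#' (`pre`, `within`, `post`, or `outcome` for the outcome block).
#'
#' @param values numeric matrix (n participants x k features) with column
#'   names, or a data.frame coercible to one.
#' @param column_kind character vector, one of `"binary"`, `"ordinal"`,
#'   `"continuous"` per column.
#' @param phase_block character vector, one of `"pre"`, `"within"`,
#'   `"post"`, `"outcome"` per column.
#' @param role `"predictor"` or `"outcome"`.
#' @return An object of class `cohort_matrix`: the numeric matrix with
#'   attributes `column_kind`, `phase_block` and `role`.
#' @examples
#' x <- cohort_matrix(matrix(c(0, 1, 1, 0.5, 2.3, -1), 3, 2,
#'                           dimnames = list(NULL, c("smoker", "ast_alt"))),
#'                    column_kind = c("binary", "continuous"),
#'                    phase_block = c("pre", "within"))
#' @export
cohort_matrix <- function(values, column_kind, phase_block,
                          role = c("predictor", "outcome")) {
  role <- match.arg(role)
  if (is.data.frame(values)) values <- as.matrix(values)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(colnames(values)))
    stop("'values' must have column names")
  if (anyDuplicated(colnames(values)))
    stop("duplicate column names: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "))
  if (nrow(values) < 2L) stop("a cohort needs at least 2 rows")
  k <- ncol(values)
  column_kind <- match_per_column(column_kind, k,
                                  c("binary", "ordinal", "continuous"),
                                  "column_kind")
  phase_block <- match_per_column(phase_block, k,
                                  c("pre", "within", "post", "outcome"),
                                  "phase_block")
  if (role == "predictor" && any(phase_block == "outcome"))
    stop("predictor block cannot carry phase_block = 'outcome'")
  if (role == "outcome" && any(phase_block != "outcome"))
    stop("outcome block columns must all have phase_block = 'outcome'")
  if (anyNA(values)) {
    idx <- which(is.na(values), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing value at row %d, column '%s'; complete cases only",
                 idx[1L], colnames(values)[idx[2L]]))
  }
  for (j in which(column_kind == "binary")) {
    if (!all(values[, j] %in% c(0, 1)))
      stop(sprintf("binary column '%s' contains values outside {0, 1}",
                   colnames(values)[j]))
  }
  structure(values, column_kind = column_kind, phase_block = phase_block,
            role = role, class = c("cohort_matrix", "matrix", "array"))
}

match_per_column <- function(x, k, levels, what) {
  if (length(x) == 1L) x <- rep(x, k)
  if (length(x) != k)
    stop(sprintf("'%s' must have length 1 or %d", what, k))
  bad <- setdiff(unique(x), levels)
  if (length(bad))
    stop(sprintf("invalid %s value(s): %s", what, paste(bad, collapse = ", ")))
  x
}

#' @export
print.cohort_matrix <- function(x, ...) {
  cat(sprintf("<cohort_matrix> %d participants x %d features (%s block)\n",
              nrow(x), ncol(x), attr(x, "role")))
  tab <- table(attr(x, "phase_block"))
  cat("  phases: ", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Strip cohort metadata, returning the bare numeric matrix
#' @param x a `cohort_matrix`
#' @param ... unused
#' @export
as.matrix.cohort_matrix <- function(x, ...) {
  attributes(x) <- list(dim = dim(x), dimnames = dimnames(x))
  x
}

#' Read a cohort block from CSV plus a column-metadata file
#'
#' The data file is a plain CSV with a header row, one row per participant,
#' period decimal separator. The metadata file is YAML with one key per
#' column giving `kind` and `phase_block`, plus a top-level `role`:
#'
#' ```yaml
#' role: predictor
#' columns:
#'   smoker:  {kind: binary, phase_block: pre}
#'   ast_alt: {kind: continuous, phase_block: within}
#' ```
#'
#' Missing cells are rejected (complete-case analysis; no imputation).
#'
#' @param path CSV file path.
#' @param metadata_path YAML metadata file path.
#' @return A [cohort_matrix()].
#' @export
read_cohort_csv <- function(path, metadata_path) {
  meta <- yaml::read_yaml(metadata_path)
  if (is.null(meta$columns) || is.null(meta$role))
    stop("metadata must contain 'role' and 'columns'")
  df <- utils::read.csv(path, check.names = FALSE)
  missing_meta <- setdiff(names(df), names(meta$columns))
  if (length(missing_meta))
    stop("column(s) absent from metadata: ",
         paste(missing_meta, collapse = ", "))
  missing_data <- setdiff(names(meta$columns), names(df))
  if (length(missing_data))
    stop("metadata column(s) absent from data: ",
         paste(missing_data, collapse = ", "))
  for (nm in names(df)) {
    if (!is.numeric(df[[nm]]))
      stop(sprintf("column '%s' is not numeric (empty cells or text?)", nm))
  }
  if (anyNA(df)) {
    idx <- which(is.na(df), arr.ind = TRUE)[1L, ]
    stop(sprintf("empty cell at row %d, column '%s'",
                 idx[1L], names(df)[idx[2L]]))
  }
  ord <- names(df)
  cohort_matrix(as.matrix(df),
                column_kind = unname(vapply(meta$columns[ord], `[[`, "", "kind")),
                phase_block = unname(vapply(meta$columns[ord], `[[`, "", "phase_block")),
                role = meta$role)
}

#' Write a cohort block as CSV plus a metadata YAML
#'
#' Inverse of [read_cohort_csv()]: a written block reads back with
#' identical values and metadata.
#'
#' @param x a `cohort_matrix`
#' @param path output CSV path
#' @param metadata_path output YAML path
#' @return Invisibly, `c(path, metadata_path)`.
#' @export
write_cohort_csv <- function(x, path, metadata_path) {
  stopifnot(inherits(x, "cohort_matrix"))
  utils::write.csv(as.data.frame(as.matrix(x)), path, row.names = FALSE)
  cols <- mapply(function(k, b) list(kind = k, phase_block = b),
                 attr(x, "column_kind"), attr(x, "phase_block"),
                 SIMPLIFY = FALSE)
  names(cols) <- colnames(x)
  yaml::write_yaml(list(role = attr(x, "role"), columns = cols),
                   metadata_path)
  invisible(c(path, metadata_path))
}

#' Check that predictor and outcome blocks describe the same participants
#' @param x predictor `cohort_matrix`
#' @param y outcome `cohort_matrix`
#' @return Invisibly TRUE; errors on mismatch.
#' @export
check_cohort_pair <- function(x, y) {
  if (nrow(x) != nrow(y))
    stop(sprintf("dimension mismatch: predictor block has %d rows, outcome block %d",
                 nrow(x), nrow(y)))
  if (attr(x, "role") != "predictor" || attr(y, "role") != "outcome")
    stop("expected a (predictor, outcome) pair of blocks")
  invisible(TRUE)
}
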