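#' Columns with a reserved meaning in sample tables
#'
#' Sample tables are ordinary data frames with one row per sample.  Numeric
#' columns are treated as network variables unless they carry one of the
#' reserved names below, which hold sample metadata instead.
#'
#' @format A character vector: `sample_id` (unique sample identifier),
#'   `group` (two-level group label), `pair_key` (identifier linking the two
#'   measurements of one subject across conditions), `stage` (synonym of
#'   `group` used by the longitudinal generators).
#' @export
reserved_columns <- c("sample_id", "group", "pair_key", "stage")

# Parse a samples x variables data frame into the internal matrix form.
# Returns list(values, sample_ids, var_labels, group, pair_key).
sm_parse <- function(data, vars = NULL, min_samples = 3L, min_vars = 2L,
                     require_group = FALSE) {
  if (!is.data.frame(data)) {
    abort("`data` must be a data frame of samples by variables.")
  }
  data <- as_tibble(data)
  if (is.null(vars)) {
    vars <- setdiff(names(data)[vapply(data, is.numeric, logical(1))],
                    reserved_columns)
  }
  if (anyDuplicated(vars)) {
    abort(paste0("Duplicate variable labels: ",
                 paste(unique(vars[duplicated(vars)]), collapse = ", ")))
  }
  missing_vars <- setdiff(vars, names(data))
  if (length(missing_vars)) {
    abort(paste0("Variables not found in `data`: ",
                 paste(missing_vars, collapse = ", ")))
  }
  X <- as.matrix(data[vars])
  if (!is.numeric(X)) {
    bad <- vars[!vapply(data[vars], is.numeric, logical(1))]
    abort(paste0("Non-numeric variable column(s): ",
                 paste(bad, collapse = ", ")))
  }
  if (anyNA(X)) {
    bad <- vars[colSums(is.na(X)) > 0]
    abort(paste0("Missing values in variable(s): ",
                 paste(bad, collapse = ", "),
                 ". Resolve missingness upstream; values are not imputed."))
  }
  if (nrow(X) < min_samples) {
    abort(paste0("At least ", min_samples, " samples required, got ", nrow(X), "."))
  }
  if (ncol(X) < min_vars) {
    abort(paste0("At least ", min_vars, " variables required, got ", ncol(X), "."))
  }
  sample_ids <- if ("sample_id" %in% names(data)) {
    as.character(data$sample_id)
  } else {
    as.character(seq_len(nrow(X)))
  }
  if (anyDuplicated(sample_ids)) {
    abort("`sample_id` values must be unique.")
  }
  group <- if ("group" %in% names(data)) as.character(data$group) else NULL
  if (require_group && is.null(group)) {
    abort("`data` must contain a `group` column.")
  }
  pair_key <- if ("pair_key" %in% names(data)) as.character(data$pair_key) else NULL
  rownames(X) <- sample_ids
  list(values = X, sample_ids = sample_ids, var_labels = vars,
       group = group, pair_key = pair_key)
}

# Error if any variable is constant (association undefined).
check_nonconstant <- function(X) {
  rng <- apply(X, 2, function(v) diff(range(v)))
  if (any(rng == 0)) {
    abort(paste0("Constant variable(s): ",
                 paste(colnames(X)[rng == 0], collapse = ", "),
                 ". Correlation is undefined for constant columns."))
  }
  invisible(X)
}

#' Read a samples-by-variables table from CSV/TSV
#'
#' The delimiter is auto-detected from the file extension (`.tsv`/`.tab` are
#' tab-separated, anything else comma-separated).  The header row holds the
#' variable labels; the optional reserved columns `sample_id`, `group` and
#' `pair_key` are kept as metadata (see [reserved_columns]).
#'
#' @param path Path to a delimited text file with a header row.
#' @param vars Optional character vector naming the variable columns; by
#'   default every non-reserved numeric column is used.
#' @return A validated tibble (one row per sample).
#' @export
read_sample_matrix <- function(path, vars = NULL) {
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path))
  }
  delim <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  data <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                            name_repair = "minimal", progress = FALSE)
  if (anyDuplicated(names(data))) {
    abort(paste0("Duplicate column names in ", path, ": ",
                 paste(unique(names(data)[duplicated(names(data))]), collapse = ", ")))
  }
  candidate <- vars %||% setdiff(names(data), reserved_columns)
  for (v in candidate) {
    col <- data[[v]]
    if (!is.numeric(col)) {
      bad_row <- which(is.na(suppressWarnings(as.numeric(col))) & !is.na(col))[1]
      abort(paste0("Non-numeric cell in column `", v, "`",
                   if (!is.na(bad_row)) paste0(", row ", bad_row), "."))
    }
  }
  sm_parse(data, vars = vars) # validate
  data
}

#' Write a samples-by-variables table to CSV/TSV
#'
#' @param data A data frame as accepted by [read_sample_matrix()].
#' @param path Output path; extension selects the delimiter.
#' @return `path`, invisibly.
#' @export
write_sample_matrix <- function(data, path) {
  if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) {
    readr::write_tsv(data, path)
  } else {
    readr::write_csv(data, path)
  }
  invisible(path)
}
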