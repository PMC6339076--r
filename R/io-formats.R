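#' Read a multivariate series from delimited text
#'
#' Comma-delimited UTF-8 with a required header row, matching the layout of
#' field data loggers: one optional timestamp column plus numeric variable
#' columns.  Columns are matched by name, so file column order does not
#' matter.  Timestamps are kept as verbatim labels — lenient by design, since
#' logger exports mix date formats — and are never used in matching.
#'
#' @param path file path.
#' @param variables variable column names, in the order they should be used
#'   (default: every column except the timestamp column, in file order).
#' @param timestamp timestamp column name, or NULL when there is none.
#'   Defaults to the first column whose values are not parseable as numbers.
#' @param id series identifier (default: file name).
#' @return a [multivariate_series()].
#' @export
read_series_csv <- function(path, variables = NULL, timestamp = NULL,
                            id = NULL) {
  if (!file.exists(path)) {
    slcss_abort(sprintf("file not found: %s", path), "slcss_error_io")
  }
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (is.null(timestamp) && ncol(df) > 1) {
    first_numeric <- nrow(df) == 0 ||
      !anyNA(suppressWarnings(as.numeric(df[[1]])))
    if (!first_numeric) timestamp <- names(df)[1]
  }
  if (!is.null(timestamp) && !timestamp %in% names(df)) {
    slcss_abort(sprintf("declared timestamp column '%s' missing from %s",
                        timestamp, path), "slcss_error_io")
  }
  if (is.null(variables)) variables <- setdiff(names(df), timestamp)
  missing <- setdiff(variables, names(df))
  if (length(missing)) {
    slcss_abort(sprintf("declared column(s) missing from %s: %s", path,
                        paste(missing, collapse = ", ")), "slcss_error_io")
  }
  cols <- list()
  for (v in variables) {
    raw <- df[[v]]
    num <- suppressWarnings(as.numeric(raw))
    if (nrow(df) > 0 && anyNA(num)) {
      bad <- which(is.na(num))[1]
      slcss_abort(sprintf("non-numeric cell in %s at row %d, column '%s': %s",
                          path, bad, v, deparse(as.character(raw[bad]))),
                  "slcss_error_io")
    }
    cols[[v]] <- num
  }
  multivariate_series(
    cols, id = id %||% sub("\\.[^.]*$", "", basename(path)),
    timestamps = if (!is.null(timestamp)) as.character(df[[timestamp]])
  )
}

#' Read FASTA records as symbol sequences
#'
#' Standard FASTA (header lines starting with `>`, wrapped sequence lines);
#' residues are folded to upper case and the identifier is the first
#' whitespace-delimited header token.  An empty file yields an empty list.
#'
#' @param path file path.
#' @return list of [symbol_sequence()]s, one per record.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    slcss_abort(sprintf("file not found: %s", path), "slcss_error_io")
  }
  lines <- readLines(path, warn = FALSE)
  meaningful <- lines[nzchar(trimws(lines))]
  if (length(meaningful) == 0) return(list())
  if (!startsWith(meaningful[1], ">")) {
    slcss_abort(sprintf("sequence data before any FASTA header in %s", path),
                "slcss_error_io")
  }
  set <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1)
  out <- lapply(seq_along(set), function(k) {
    symbol_sequence(strsplit(toupper(as.character(set[[k]])), "")[[1]],
                    id = ids[k])
  })
  out
}

#' Write an LCSS result to JSON or TSV
#'
#' JSON carries the full result (parameters, per-pass and per-stage lengths,
#' comparison count, matched pairs with values/timestamps) and round-trips
#' through [read_result()].  TSV is the tabular view: one matched pair per
#' row with positions `i`, `j` and the matched values per variable.
#'
#' @param result an `lcss_result` (or `mlcss_result`).
#' @param path output file path.
#' @param format `"json"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_result <- function(result, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  stopifnot(inherits(result, "lcss_result"))
  dir <- dirname(path)
  if (!dir.exists(dir)) {
    slcss_abort(sprintf("directory does not exist: %s", dir), "slcss_error_io")
  }
  if (format == "tsv") {
    utils::write.table(result$pairs, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(path))
  }
  params <- result$parameters
  params$spec <- list(mode = params$spec$mode, epsilon = params$spec$epsilon)
  params$sigma <- if (is.finite(params$sigma)) params$sigma else "unbounded"
  payload <- list(
    length = result$length,
    best_start = result$best_start,
    anchor_length = result$anchor_length,
    stage_lengths = as.list(result$stage_lengths),
    pass_lengths = result$pass_lengths,
    comparisons = result$comparisons,
    parameters = params,
    pairs = result$pairs
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read back a JSON result written by [write_result()]
#'
#' @param path JSON file path.
#' @return list with the fields of the written result (`length`,
#'   `best_start`, `stage_lengths`, `pass_lengths`, `comparisons`,
#'   `parameters`, `pairs` as a data.frame).
#' @export
read_result <- function(path) {
  if (!file.exists(path)) {
    slcss_abort(sprintf("file not found: %s", path), "slcss_error_io")
  }
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$pass_lengths <- as.integer(x$pass_lengths)
  if (is.list(x$pairs) && !is.data.frame(x$pairs)) {
    x$pairs <- as.data.frame(x$pairs)
  }
  x
}
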