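#' Univariate symbol sequence
#'
#' An ordered series of mutually comparable values: characters (e.g. DNA
#' residues) or real numbers (e.g. one sensor channel).
#'
#' @param values character or numeric vector of symbols, in order.
#' @param id identifier string.
#' @return An object of class `symbol_sequence` with fields `id` and `values`.
#' @examples
#' symbol_sequence(strsplit("AEBACFDADB", "")[[1]], id = "S")
#' @export
symbol_sequence <- function(values, id = "seq") {
  if (is.factor(values)) values <- as.character(values)
  if (!is.character(values) && !is.numeric(values)) {
    slcss_abort("sequence values must be characters or numbers",
                "slcss_error_bad_values")
  }
  structure(list(id = as.character(id)[1], values = values),
            class = "symbol_sequence")
}

#' @export
length.symbol_sequence <- function(x) length(x$values)

#' @export
print.symbol_sequence <- function(x, ...) {
  cat(sprintf("<symbol_sequence '%s'> length %d\n", x$id, length(x)))
  v <- x$values
  shown <- if (length(v) > 20) c(as.character(v[1:20]), "...") else as.character(v)
  cat(" ", paste(shown, collapse = " "), "\n")
  invisible(x)
}

#' Multivariate series
#'
#' `h >= 1` aligned variables (columns) of identical length `m`, with optional
#' timestamps.  Timestamps are carried as row labels only; they never take
#' part in matching.  Monotonicity is enforced only when timestamps are
#' supplied as numbers or time points; character labels are kept verbatim.
#'
#' @param columns named list of equal-length character/numeric vectors, or a
#'   data.frame (each column one variable).
#' @param id identifier string.
#' @param timestamps optional vector of length `m`.
#' @return An object of class `multivariate_series` with fields `id`,
#'   `variable_names`, `columns`, `timestamps`.
#' @export
multivariate_series <- function(columns, id = "series", timestamps = NULL) {
  if (is.data.frame(columns)) columns <- as.list(columns)
  if (!is.list(columns) || length(columns) < 1) {
    slcss_abort("need at least one variable column", "slcss_error_bad_values")
  }
  nm <- names(columns)
  if (is.null(nm) || any(!nzchar(nm))) {
    slcss_abort("every variable column must be named", "slcss_error_bad_values")
  }
  columns <- lapply(columns, function(v) if (is.factor(v)) as.character(v) else v)
  m <- length(columns[[1]])
  lens <- vapply(columns, length, integer(1))
  if (any(lens != m)) {
    slcss_abort(sprintf("columns differ in length: %s",
                        paste(sprintf("%s=%d", nm, lens), collapse = ", ")),
                "slcss_error_ragged")
  }
  if (!is.null(timestamps)) {
    if (length(timestamps) != m) {
      slcss_abort("timestamps must have one entry per row",
                  "slcss_error_bad_timestamps")
    }
    if ((is.numeric(timestamps) || inherits(timestamps, "POSIXt") ||
         inherits(timestamps, "Date")) && m > 1 &&
        any(diff(as.numeric(timestamps)) < 0)) {
      slcss_abort("timestamps must be non-decreasing",
                  "slcss_error_bad_timestamps")
    }
  }
  structure(list(id = as.character(id)[1], variable_names = nm,
                 columns = columns, timestamps = timestamps),
            class = "multivariate_series")
}

#' @export
length.multivariate_series <- function(x) length(x$columns[[1]])

#' @export
print.multivariate_series <- function(x, ...) {
  cat(sprintf("<multivariate_series '%s'> %d rows x %d variables (%s)\n",
              x$id, length(x), length(x$columns),
              paste(x$variable_names, collapse = ", ")))
  invisible(x)
}

#' @export
as.data.frame.multivariate_series <- function(x, ...) {
  df <- as.data.frame(x$columns, optional = TRUE)
  if (!is.null(x$timestamps)) df <- cbind(timestamp = x$timestamps, df)
  df
}

#' Extract one variable of a multivariate series as a symbol sequence
#'
#' @param x a `multivariate_series`.
#' @param variable variable name or column index.
#' @return a [symbol_sequence()].
#' @export
series_variable <- function(x, variable) {
  stopifnot(inherits(x, "multivariate_series"))
  if (is.numeric(variable)) variable <- x$variable_names[variable]
  if (is.na(variable) || !variable %in% x$variable_names) {
    slcss_abort(sprintf("variable '%s' not found in series '%s' (has: %s)",
                        variable, x$id,
                        paste(x$variable_names, collapse = ", ")),
                "slcss_error_unknown_variable")
  }
  symbol_sequence(x$columns[[variable]],
                  id = paste(x$id, variable, sep = ":"))
}

#' Equality specification
#'
#' The predicate used by every matching operation.  `exact` mode is plain
#' equality and is transitive; `tolerance` mode accepts `|a - b| <= epsilon`
#' for numeric values and is deliberately not transitive (documented, not an
#' error).  Default is exact, which is what raw sensor readings and symbol
#' sequences use.
#'
#' @param mode `"exact"` or `"tolerance"`.
#' @param epsilon non-negative tolerance; scalar or named per-variable vector.
#'   Must be 0 in exact mode.
#' @export
eq_spec <- function(mode = c("exact", "tolerance"), epsilon = 0) {
  mode <- match.arg(mode)
  if (any(epsilon < 0)) {
    slcss_abort("epsilon must be non-negative", "slcss_error_bad_spec")
  }
  if (mode == "exact" && any(epsilon != 0)) {
    slcss_abort("exact mode requires epsilon = 0", "slcss_error_bad_spec")
  }
  structure(list(mode = mode, epsilon = epsilon), class = "eq_spec")
}

# per-variable epsilon lookup (scalar recycles; named vector matched by name)
spec_epsilon <- function(spec, variable = NULL) {
  eps <- spec$epsilon
  if (length(eps) == 1 || is.null(variable)) return(unname(eps[1]))
  if (!is.null(names(eps)) && variable %in% names(eps)) return(unname(eps[[variable]]))
  unname(eps[1])
}

#' Element equality under an [eq_spec()]
#'
#' Vectorized over `a` and `b`.  Symbols can only be compared with symbols and
#' numbers with numbers; mixing the two is a typed error naming both operands.
#' Tolerance mode requires numeric operands.
#'
#' @param a,b symbols (character) or numbers.
#' @param spec an [eq_spec()].
#' @return logical vector.
#' @examples
#' eq(35, 35)                                  # TRUE
#' eq(82, 81)                                  # FALSE
#' eq(0.50, 0.501, eq_spec("tolerance", 0.01)) # TRUE
#' @export
eq <- function(a, b, spec = eq_spec()) {
  stopifnot(inherits(spec, "eq_spec"))
  if (is.factor(a)) a <- as.character(a)
  if (is.factor(b)) b <- as.character(b)
  if (is.character(a) != is.character(b)) {
    slcss_abort(sprintf("cannot compare a symbol with a number: %s vs %s",
                        deparse(a[1]), deparse(b[1])),
                "slcss_error_incomparable")
  }
  if (spec$mode == "tolerance") {
    if (is.character(a)) {
      slcss_abort("tolerance mode requires numeric values",
                  "slcss_error_incomparable")
    }
    return(abs(a - b) <= spec_epsilon(spec))
  }
  a == b
}

# Encode a pair of value vectors for the compiled kernels: characters become
# integer codes over the union (exact mode only); numerics pass through with
# the spec's epsilon.
encode_pair <- function(s, t, spec, variable = NULL) {
  if (is.factor(s)) s <- as.character(s)
  if (is.factor(t)) t <- as.character(t)
  if (is.character(s) != is.character(t)) {
    slcss_abort("cannot match symbols against numbers",
                "slcss_error_incomparable")
  }
  if (is.character(s)) {
    if (spec$mode == "tolerance") {
      slcss_abort("tolerance mode requires numeric values",
                  "slcss_error_incomparable")
    }
    lev <- unique(c(s, t))
    list(s = as.numeric(match(s, lev)), t = as.numeric(match(t, lev)), eps = 0)
  } else {
    eps <- if (spec$mode == "tolerance") spec_epsilon(spec, variable) else 0
    list(s = as.numeric(s), t = as.numeric(t), eps = eps)
  }
}

#' Match trace
#'
#' The ordered list of matched index pairs (the positional record of a common
#' subsequence).  Pairs are strictly increasing in both coordinates and, for
#' traces produced by the windowed pass, consecutive pairs obey the window
#' discipline `j[k+1] - (j[k] + 1) <= sigma - 1`.  All coordinates are 0-based
#' positions in the original sequences, even when the pass started at a suffix
#' offset.
#'
#' @param i,j integer vectors of matched 0-based positions in S and T.
#' @param sigma window parameter in force (`Inf` = unbounded).
#' @param start_offset suffix start `a` of the pass that produced the trace.
#' @return An object of class `match_trace`.
#' @export
match_trace <- function(i = integer(0), j = integer(0), sigma = Inf,
                        start_offset = 0L) {
  i <- as.integer(i); j <- as.integer(j)
  if (length(i) != length(j)) {
    slcss_abort("i and j must have equal length", "slcss_error_bad_trace")
  }
  if (length(i) && (any(i < 0) || any(j < 0))) {
    slcss_abort("trace positions are 0-based and non-negative",
                "slcss_error_bad_trace")
  }
  if (length(i) > 1 && (any(diff(i) <= 0) || any(diff(j) <= 0))) {
    slcss_abort("trace must be strictly increasing in both coordinates",
                "slcss_error_bad_trace")
  }
  if (is.finite(sigma) && length(j) > 1 && any(diff(j) > sigma)) {
    slcss_abort(sprintf("trace violates window discipline for sigma = %d",
                        as.integer(sigma)),
                "slcss_error_bad_trace")
  }
  structure(list(pairs = data.frame(i = i, j = j), sigma = sigma,
                 start_offset = as.integer(start_offset)),
            class = "match_trace")
}

#' @export
length.match_trace <- function(x) nrow(x$pairs)

#' @export
as.data.frame.match_trace <- function(x, ...) x$pairs

#' @export
print.match_trace <- function(x, ...) {
  cat(sprintf("<match_trace> %d pairs (sigma = %s, start = %d)\n",
              length(x), format(x$sigma), x$start_offset))
  if (length(x)) {
    cat(" ", paste(sprintf("(%d,%d)", x$pairs$i, x$pairs$j), collapse = " "),
        "\n")
  }
  invisible(x)
}

# container for sliding_lcss()/mlcss() output; built internally
new_lcss_result <- function(best_trace, best_start, pass_lengths, comparisons,
                            parameters, pairs = NULL, stage_lengths = NULL,
                            anchor_length = NULL, class = character(0)) {
  res <- structure(list(
    best_trace = best_trace,
    length = length(best_trace),
    best_start = as.integer(best_start),
    pass_lengths = as.integer(pass_lengths),
    comparisons = comparisons,
    parameters = parameters,
    pairs = pairs,
    stage_lengths = stage_lengths,
    anchor_length = anchor_length
  ), class = c(class, "lcss_result"))
  stopifnot(res$length == nrow(res$best_trace$pairs))
  res
}

#' @export
print.lcss_result <- function(x, ...) {
  cat(sprintf("<%s> length %d (best start %d)\n",
              class(x)[1], x$length, x$best_start))
  if (!is.null(x$stage_lengths)) {
    cat("  per-stage lengths:",
        paste(sprintf("%s=%d", names(x$stage_lengths), x$stage_lengths),
              collapse = ", "), "\n")
  }
  cat(sprintf("  passes: %d (lengths %s)\n", length(x$pass_lengths),
              paste(x$pass_lengths, collapse = " ")))
  cat(sprintf("  comparisons: %s\n", format(x$comparisons, big.mark = ",")))
  invisible(x)
}
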