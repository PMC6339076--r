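#' Refine a match trace by agreement on further variables
#'
#' Stage two of the multivariate pipeline: the trace found on the anchor
#' variable is filtered to the pairs whose rows also agree on every requested
#' remaining variable.  The surviving set is exactly
#' `{(i, j) in trace : all requested variables equal}`, so the operation is
#' idempotent, monotone non-increasing in trace length, and independent of
#' the order the variables are processed in.
#'
#' @param trace a [match_trace()] whose pairs index valid rows of `S`, `T`.
#' @param S,T `multivariate_series`.
#' @param variables character vector of variable names to require agreement
#'   on (default: every variable but the first).  Zero variables = identity.
#' @param spec an [eq_spec()].
#' @return the refined [match_trace()]; the input is not modified.
#' @export
refine_trace <- function(trace, S, T,
                         variables = setdiff(S$variable_names,
                                             S$variable_names[1]),
                         spec = eq_spec()) {
  stopifnot(inherits(trace, "match_trace"),
            inherits(S, "multivariate_series"),
            inherits(T, "multivariate_series"))
  for (v in variables) {
    if (!v %in% S$variable_names || !v %in% T$variable_names) {
      slcss_abort(sprintf("variable '%s' not present in both series", v),
                  "slcss_error_unknown_variable")
    }
  }
  if (length(trace) == 0 || length(variables) == 0) return(trace)
  i <- trace$pairs$i; j <- trace$pairs$j
  if (any(i >= length(S)) || any(j >= length(T))) {
    slcss_abort("trace indexes rows beyond the series", "slcss_error_bad_trace")
  }
  keep <- rep(TRUE, length(i))
  for (v in variables) {
    vspec <- if (spec$mode == "tolerance") {
      eq_spec("tolerance", spec_epsilon(spec, v))
    } else {
      spec
    }
    keep <- keep & eq(S$columns[[v]][i + 1L], T$columns[[v]][j + 1L], vspec)
  }
  # deleting interior pairs can widen j-gaps beyond the original window, so
  # the refined trace carries no window constraint
  match_trace(i[keep], j[keep], sigma = Inf,
              start_offset = trace$start_offset)
}

#' Multivariate sliding-window LCSS
#'
#' The full anchor-then-filter pipeline: [sliding_lcss()] on the anchor
#' variable (the first column by default), then [refine_trace()] over the
#' remaining variables in column order.  The result records the per-stage
#' lengths — e.g. a temperature trace of length 8 reduced to 7 by a
#' disagreeing humidity pair — along with the stage-1 pass diagnostics.
#'
#' The anchor choice materially changes the result (the heuristic searches
#' only on the anchor); it is exposed rather than hidden.
#'
#' @param S,T `multivariate_series` sharing variable names.
#' @param sigma sliding window control parameter.
#' @param anchor anchor variable name or index (default: first column).
#' @param normalize apply joint-pair [normalize_pair()] first? (default FALSE:
#'   raw values are matched).
#' @param spec an [eq_spec()].
#' @inheritParams sliding_lcss
#' @return an `mlcss_result` (subclass of `lcss_result`): `length` is the
#'   final refined length, `anchor_length` the stage-1 length,
#'   `stage_lengths` the named per-stage history, `pairs` a data.frame with
#'   matched positions, timestamps (when present) and per-variable values.
#' @examples
#' s <- multivariate_series(list(temp = c(1, 2, 3), hum = c(5, 6, 7)))
#' mlcss(s, s, sigma = 3)$length
#' @export
mlcss <- function(S, T, sigma = 3, anchor = NULL, max_start = NULL,
                  start_fraction = 0.5, early_stop = TRUE,
                  normalize = FALSE, spec = eq_spec()) {
  stopifnot(inherits(S, "multivariate_series"),
            inherits(T, "multivariate_series"))
  if (!identical(S$variable_names, T$variable_names)) {
    slcss_abort(sprintf(
      "series disagree on variables: only in S: [%s]; only in T: [%s]",
      paste(setdiff(S$variable_names, T$variable_names), collapse = ", "),
      paste(setdiff(T$variable_names, S$variable_names), collapse = ", ")),
      "slcss_error_variable_mismatch")
  }
  if (normalize) {
    np <- normalize_pair(S, T, scope = "joint-pair")
    S <- np$S; T <- np$T
  }
  anchor <- if (is.null(anchor)) S$variable_names[1] else anchor
  if (is.numeric(anchor)) anchor <- S$variable_names[anchor]
  if (is.na(anchor) || !anchor %in% S$variable_names) {
    slcss_abort(sprintf("anchor variable '%s' not found", anchor),
                "slcss_error_unknown_variable")
  }

  aspec <- if (spec$mode == "tolerance") {
    eq_spec("tolerance", spec_epsilon(spec, anchor))
  } else {
    spec
  }
  stage1 <- sliding_lcss(S$columns[[anchor]], T$columns[[anchor]],
                         sigma = sigma, max_start = max_start,
                         start_fraction = start_fraction,
                         early_stop = early_stop, spec = aspec)

  rest <- setdiff(S$variable_names, anchor)
  stage_lengths <- stats::setNames(stage1$length, anchor)
  trace <- stage1$best_trace
  refine_comparisons <- 0
  for (v in rest) {  # refinement commutes; column order kept for diagnostics
    refine_comparisons <- refine_comparisons + length(trace)
    trace <- refine_trace(trace, S, T, variables = v, spec = spec)
    stage_lengths <- c(stage_lengths, stats::setNames(length(trace), v))
  }

  i <- trace$pairs$i; j <- trace$pairs$j
  pairs <- data.frame(i = i, j = j)
  if (!is.null(S$timestamps)) pairs$S_timestamp <- S$timestamps[i + 1L]
  if (!is.null(T$timestamps)) pairs$T_timestamp <- T$timestamps[j + 1L]
  for (v in S$variable_names) {
    pairs[[paste0("S_", v)]] <- S$columns[[v]][i + 1L]
    pairs[[paste0("T_", v)]] <- T$columns[[v]][j + 1L]
  }

  new_lcss_result(
    best_trace = trace, best_start = stage1$best_start,
    pass_lengths = stage1$pass_lengths,
    comparisons = stage1$comparisons + refine_comparisons,
    parameters = c(stage1$parameters,
                   list(anchor = anchor, normalize = normalize)),
    pairs = pairs, stage_lengths = stage_lengths,
    anchor_length = stage1$length, class = "mlcss_result"
  )
}

#' Similarity index of a result
#'
#' Final matched length normalized by the shorter input's length, in
#' `[0, 1]`.  Defined as 0 when either input is empty.
#'
#' @param result an `lcss_result`.
#' @param m,n the two input lengths.
#' @export
similarity_index <- function(result, m, n) {
  stopifnot(inherits(result, "lcss_result"))
  if (m <= 0 || n <= 0) return(0)
  result$length / min(m, n)
}
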