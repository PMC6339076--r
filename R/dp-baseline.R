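#' Dynamic-programming LCS baseline
#'
#' The classical quadratic algorithm: fills the `(m+1) x (n+1)` similarity
#' table of optimal prefix LCS lengths and (optionally) walks one canonical
#' traceback.  Under exact equality the returned length is the true optimum,
#' which makes this the internal oracle against which the windowed heuristic
#' is bounded.  With a tolerance spec the non-transitive predicate voids the
#' optimality guarantee; the result is flagged (`optimal_guaranteed = FALSE`)
#' rather than rejected.
#'
#' Traceback tie-break: diagonal (match) first, then up, then left — one
#' deterministic canonical trace.  The full table is materialized only on
#' request; length-only calls use two rolling rows.
#'
#' @param A,B [symbol_sequence()]s (or plain vectors).
#' @param spec an [eq_spec()].
#' @param trace return a traceback [match_trace()]? (default TRUE)
#' @param table return the full DP table? (default FALSE)
#' @return list with `length`, `trace` (when requested), `table` (when
#'   requested), `comparisons` (`m * n` table-fill predicate evaluations) and
#'   `optimal_guaranteed`.
#' @examples
#' dp_lcs(strsplit("AEBACFDADB", "")[[1]], strsplit("CABDACDADB", "")[[1]])$length
#' @export
dp_lcs <- function(A, B, spec = eq_spec(), trace = TRUE, table = FALSE) {
  av <- if (inherits(A, "symbol_sequence")) A$values else A
  bv <- if (inherits(B, "symbol_sequence")) B$values else B
  enc <- encode_pair(av, bv, spec)
  out <- cpp_dp_lcs(matrix(enc$s, ncol = 1), matrix(enc$t, ncol = 1),
                    enc$eps, trace, table)
  finish_dp(out, trace, table, spec)
}

#' Dynamic-programming LCS over row tuples of two multivariate series
#'
#' Rows are treated as composite symbols: two rows are equal iff every
#' variable agrees under the spec.  This gives the optimality reference for
#' the anchor-then-refine multivariate pipeline (whose result can never
#' exceed it — though the converse does not hold).
#'
#' @param S,T `multivariate_series` sharing variable names.
#' @inheritParams dp_lcs
#' @export
dp_lcs_multivariate <- function(S, T, spec = eq_spec(), trace = TRUE,
                                table = FALSE) {
  stopifnot(inherits(S, "multivariate_series"),
            inherits(T, "multivariate_series"))
  if (!identical(S$variable_names, T$variable_names)) {
    slcss_abort(sprintf(
      "series disagree on variables: only in S: [%s]; only in T: [%s]",
      paste(setdiff(S$variable_names, T$variable_names), collapse = ", "),
      paste(setdiff(T$variable_names, S$variable_names), collapse = ", ")),
      "slcss_error_variable_mismatch")
  }
  h <- length(S$variable_names)
  m <- length(S); n <- length(T)
  Am <- matrix(0, nrow = m, ncol = h)
  Bm <- matrix(0, nrow = n, ncol = h)
  eps <- numeric(h)
  for (k in seq_len(h)) {
    v <- S$variable_names[k]
    enc <- encode_pair(S$columns[[v]], T$columns[[v]], spec, variable = v)
    Am[, k] <- enc$s
    Bm[, k] <- enc$t
    eps[k] <- enc$eps
  }
  out <- cpp_dp_lcs(Am, Bm, eps, trace, table)
  finish_dp(out, trace, table, spec)
}

finish_dp <- function(out, trace, table, spec) {
  res <- list(
    length = out$length,
    trace = if (trace) match_trace(out$i, out$j, sigma = Inf) else NULL,
    table = if (table) out$table else NULL,
    comparisons = out$comparisons,
    optimal_guaranteed = spec$mode == "exact"
  )
  if (trace) stopifnot(length(res$trace) == res$length)
  res
}
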