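#' One greedy windowed matching pass
#'
#' Scans `S` left to right from suffix start `a`.  For each element the
#' window of at most `sigma` candidate positions of `T`, counted from the
#' trace pointer TP (inclusive), is examined in order; the first equal
#' position is recorded as a match, TP moves just past it, and the scan
#' advances.  When the whole window fails, TP stays where it is and only the
#' `S` position advances — a failed element costs at most `sigma` comparisons
#' and never discards candidates for its successors.
#'
#' @param S,T [symbol_sequence()]s or plain vectors.
#' @param start suffix start `a` (0-based) in `S`.
#' @param sigma sliding window control parameter, `>= 1`; `Inf` for an
#'   unbounded window.  Small values suit slowly varying channels (e.g. air
#'   temperature); large values suit highly fluctuating series.
#' @param spec an [eq_spec()].
#' @return a [match_trace()] in original coordinates, with attribute
#'   `comparisons` (number of equality-predicate evaluations).
#' @examples
#' tr <- greedy_pass(strsplit("AEBACFDADB", "")[[1]],
#'                   strsplit("CABDACDADB", "")[[1]], sigma = 3)
#' as.data.frame(tr)
#' @export
greedy_pass <- function(S, T, start = 0L, sigma = 3, spec = eq_spec()) {
  sv <- if (inherits(S, "symbol_sequence")) S$values else S
  tv <- if (inherits(T, "symbol_sequence")) T$values else T
  check_sigma(sigma)
  m <- length(sv); n <- length(tv)
  if (start < 0 || start > m) {
    slcss_abort(sprintf("start must lie in [0, %d], got %s", m, format(start)),
                "slcss_error_bad_start")
  }
  if (m == 0 || n == 0) {
    tr <- match_trace(sigma = sigma, start_offset = start)
    attr(tr, "comparisons") <- 0
    return(tr)
  }
  enc <- encode_pair(sv, tv, spec)
  sig <- as.integer(min(sigma, n))
  out <- cpp_greedy_pass(enc$s, enc$t, as.integer(start), sig, enc$eps)
  tr <- match_trace(out$i, out$j, sigma = sigma, start_offset = start)
  attr(tr, "comparisons") <- out$comparisons
  tr
}

check_sigma <- function(sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1 || is.na(sigma) || sigma < 1) {
    slcss_abort("sigma must be a single value >= 1", "slcss_error_bad_sigma")
  }
}

#' Sliding-window LCSS of two univariate sequences
#'
#' Runs [greedy_pass()] for suffix starts `a = 0, 1, 2, ...`, keeping the
#' longest trace.  A pass replaces the incumbent only when strictly longer,
#' so the smallest best start wins ties.  Iteration stops when `a > max_start`
#' or — with `early_stop` on — as soon as the incumbent length reaches
#' `max_start`.  Match positions are always reported in original `S`
#' coordinates, so downstream refinement can look up other variables at the
#' matched rows.
#'
#' The default `max_start` is half the length of `S` (`start_fraction = 0.5`);
#' the fraction is a parameter because the appropriate restart depth is
#' data-dependent.  Early stopping is faithful to the restart loop's
#' termination condition but can forfeit longer traces from later starts;
#' disable it (and set `max_start = length(S)`) for an exhaustive search.
#'
#' @inheritParams greedy_pass
#' @param max_start largest suffix start `M` to try (default
#'   `floor(m * start_fraction)`).
#' @param start_fraction fraction of `m` used for the default `max_start`.
#' @param early_stop stop once the incumbent length reaches `max_start`?
#'   (default TRUE)
#' @param auto_order when TRUE, swap the arguments so the shorter sequence is
#'   scanned (the restart loop deletes prefixes of the first argument only);
#'   default FALSE, matching the asymmetric definition.
#' @return an object of class `lcss_result`: `best_trace`, `length`,
#'   `best_start`, `pass_lengths`, `comparisons`, `parameters`, and a
#'   `pairs` data.frame with the matched values.
#' @examples
#' r <- sliding_lcss(c(35, 39, 36, 35, 37, 36, 38, 35, 38, 36),
#'                   c(37, 35, 36, 38, 35, 37, 38, 35, 38, 36), sigma = 3)
#' r$length
#' @export
sliding_lcss <- function(S, T, sigma = 3, max_start = NULL,
                         start_fraction = 0.5, early_stop = TRUE,
                         spec = eq_spec(), auto_order = FALSE) {
  sv <- if (inherits(S, "symbol_sequence")) S$values else S
  tv <- if (inherits(T, "symbol_sequence")) T$values else T
  check_sigma(sigma)
  swapped <- FALSE
  if (auto_order && length(tv) < length(sv)) {
    tmp <- sv; sv <- tv; tv <- tmp
    swapped <- TRUE
  }
  m <- length(sv); n <- length(tv)
  M <- if (is.null(max_start)) floor(m * start_fraction) else max_start
  if (M < 0 || M > m) {
    slcss_abort(sprintf("max_start must lie in [0, %d], got %s", m, format(M)),
                "slcss_error_bad_start")
  }

  if (m == 0 || n == 0) {
    enc <- NULL
  } else {
    enc <- encode_pair(sv, tv, spec)
  }
  sig <- as.integer(min(sigma, max(n, 1)))

  best_i <- integer(0); best_j <- integer(0)
  best_len <- 0L; best_start <- 0L
  pass_lengths <- integer(0)
  comparisons <- 0
  for (a in 0:M) {
    if (early_stop && best_len >= M && length(pass_lengths) > 0) break
    if (is.null(enc)) {
      pass_lengths <- c(pass_lengths, 0L)
      break
    }
    out <- cpp_greedy_pass(enc$s, enc$t, a, sig, enc$eps)
    comparisons <- comparisons + out$comparisons
    cnt <- length(out$i)
    pass_lengths <- c(pass_lengths, cnt)
    if (cnt > best_len) {  # strict improvement only: earliest start wins ties
      best_len <- cnt
      best_i <- out$i
      best_j <- out$j
      best_start <- a
    }
  }

  trace <- match_trace(best_i, best_j, sigma = sigma,
                       start_offset = best_start)
  pairs <- data.frame(i = best_i, j = best_j)
  if (length(best_i)) {
    pairs$S_value <- sv[best_i + 1L]
    pairs$T_value <- tv[best_j + 1L]
  } else {
    pairs$S_value <- if (is.character(sv)) character(0) else numeric(0)
    pairs$T_value <- pairs$S_value
  }
  new_lcss_result(
    best_trace = trace, best_start = best_start,
    pass_lengths = pass_lengths, comparisons = comparisons,
    parameters = list(sigma = sigma, max_start = M, early_stop = early_stop,
                      spec = spec, swapped = swapped),
    pairs = pairs
  )
}

#' Number of equality-predicate evaluations behind a result
#'
#' Exact instrumentation counter: every evaluation of the element-equality
#' predicate during the windowed passes is counted.  Identical sequences with
#' early stopping cost exactly `m` comparisons (one pass, one hit per
#' element); any run is bounded by `(max_start + 1) * m * sigma`.
#'
#' @param result an `lcss_result`.
#' @return the comparison count (numeric, exact).
#' @export
comparison_count <- function(result) {
  stopifnot(inherits(result, "lcss_result"))
  result$comparisons
}
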