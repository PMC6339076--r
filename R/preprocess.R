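#' Min-max normalization of a numeric series
#'
#' Rescales values to `[0, 1]` via `(v - Tmin) / (Tmax - Tmin)`.  Sensor
#' channels recorded on different scales should be normalized before
#' similarity analysis; note that after rescaling, exact equality of real
#' values is fragile and a tolerance [eq_spec()] is usually appropriate.
#'
#' A constant column (`Tmax == Tmin`) maps to all zeros rather than erroring:
#' constant sensor channels occur in practice and must not abort a pipeline.
#'
#' @param values numeric vector, length >= 1.
#' @return list with `values` (rescaled vector), `tmin`, `tmax`.
#' @examples
#' normalize_minmax(c(35, 39, 36, 35, 37, 36, 38, 35, 38, 36))$values
#' @export
normalize_minmax <- function(values) {
  if (length(values) == 0) {
    slcss_abort("cannot normalize an empty series", "slcss_error_empty")
  }
  if (!is.numeric(values)) {
    bad <- which(is.na(suppressWarnings(as.numeric(values))))[1]
    slcss_abort(sprintf("non-numeric value at position %d: %s",
                        bad %||% 1L, deparse(values[bad %||% 1L])),
                "slcss_error_bad_values")
  }
  tmin <- min(values)
  tmax <- max(values)
  out <- if (tmax == tmin) rep(0, length(values)) else (values - tmin) / (tmax - tmin)
  list(values = out, tmin = tmin, tmax = tmax)
}

#' Min-max normalization of a series pair
#'
#' Applies [normalize_minmax()] to every variable of both series.  With the
#' default `"joint-pair"` scope the extremes are pooled over both series per
#' variable, so equal raw values stay equal after rescaling — which exact
#' matching relies on.  `"per-series"` scope rescales each series by its own
#' extremes.
#'
#' @param S,T `multivariate_series` sharing the same variable names.
#' @param scope `"joint-pair"` (default) or `"per-series"`.
#' @return list with rescaled `S`, `T` and a `report` data.frame of the
#'   `(tmin, tmax)` used per variable (and per series for per-series scope).
#' @export
normalize_pair <- function(S, T, scope = c("joint-pair", "per-series")) {
  scope <- match.arg(scope)
  stopifnot(inherits(S, "multivariate_series"),
            inherits(T, "multivariate_series"))
  if (!identical(S$variable_names, T$variable_names)) {
    slcss_abort(sprintf(
      "series disagree on variables: only in S: [%s]; only in T: [%s]",
      paste(setdiff(S$variable_names, T$variable_names), collapse = ", "),
      paste(setdiff(T$variable_names, S$variable_names), collapse = ", ")),
      "slcss_error_variable_mismatch")
  }
  rep_rows <- list()
  for (v in S$variable_names) {
    sv <- S$columns[[v]]; tv <- T$columns[[v]]
    if (!is.numeric(sv) || !is.numeric(tv)) {
      slcss_abort(sprintf("variable '%s' is not numeric", v),
                  "slcss_error_bad_values")
    }
    if (scope == "joint-pair") {
      pooled <- c(sv, tv)
      tmin <- min(pooled); tmax <- max(pooled)
      rng <- tmax - tmin
      S$columns[[v]] <- if (rng == 0) rep(0, length(sv)) else (sv - tmin) / rng
      T$columns[[v]] <- if (rng == 0) rep(0, length(tv)) else (tv - tmin) / rng
      rep_rows[[length(rep_rows) + 1L]] <-
        data.frame(variable = v, series = "both", tmin = tmin, tmax = tmax,
                   scope = scope)
    } else {
      ns <- normalize_minmax(sv); nt <- normalize_minmax(tv)
      S$columns[[v]] <- ns$values
      T$columns[[v]] <- nt$values
      rep_rows[[length(rep_rows) + 1L]] <-
        data.frame(variable = v, series = c("S", "T"),
                   tmin = c(ns$tmin, nt$tmin), tmax = c(ns$tmax, nt$tmax),
                   scope = scope)
    }
  }
  list(S = S, T = T, report = do.call(rbind, rep_rows))
}
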