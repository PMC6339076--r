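#' Synthetic pair generator configuration
#'
#' Settings for [generate_pair()]: series of length `m` with `h` variables,
#' where each row of `S` is copied into `T` with match probability `delta`
#' (a planted match, optionally displaced by up to `d` positions) and
#' replaced otherwise.  Replacement values come from a reserved pool disjoint
#' from the value model, so non-planted positions cannot accidentally match
#' on variable 1 and the planted trace is a sharp oracle; `honest_noise`
#' switches replacements to the same distribution as the data for realistic
#' accidental matches.
#'
#' Value models: `"real"` (continuous uniform draws — real-valued sensor
#' channels, effectively duplicate-free), `"symbolic"` (alphabet of
#' `alphabet_size` letters — DNA-like), `"integer"` (uniform integers in
#' `int_range` — quantized sensor readings).
#'
#' @param m series length (rows).
#' @param h number of variables, `>= 1`.
#' @param delta planted match probability in `[0, 1]`.
#' @param value_model `"real"`, `"symbolic"` or `"integer"`.
#' @param alphabet_size symbolic alphabet size `k` (2..26).
#' @param int_range length-2 integer range for the integer model.
#' @param displacement max positional jitter `d` of planted matches; must be
#'   `< m`.
#' @param delta2 probability that each additional variable of a planted row
#'   is copied exactly (default 1); smaller values plant cross-variable
#'   disagreements that exercise refinement deletions.
#' @param honest_noise draw replacements from the data distribution instead
#'   of the disjoint pool?
#' @param seed RNG seed; same seed, same pair.
#' @export
synthetic_config <- function(m = 500, h = 1, delta = 0.5,
                             value_model = c("real", "symbolic", "integer"),
                             alphabet_size = 4, int_range = c(30L, 40L),
                             displacement = 0, delta2 = 1,
                             honest_noise = FALSE, seed = NULL) {
  value_model <- match.arg(value_model)
  if (m < 0) slcss_abort("m must be >= 0", "slcss_error_bad_config")
  if (h < 1) slcss_abort("h must be >= 1", "slcss_error_bad_config")
  if (delta < 0 || delta > 1) {
    slcss_abort("delta must lie in [0, 1]", "slcss_error_bad_config")
  }
  if (delta2 < 0 || delta2 > 1) {
    slcss_abort("delta2 must lie in [0, 1]", "slcss_error_bad_config")
  }
  if (displacement < 0) {
    slcss_abort("displacement must be >= 0", "slcss_error_bad_config")
  }
  if (m > 0 && displacement >= m) {
    slcss_abort(sprintf("impossible displacement: d = %d >= m = %d",
                        displacement, m), "slcss_error_bad_config")
  }
  if (value_model == "symbolic" &&
      (alphabet_size < 2 || alphabet_size > 26)) {
    slcss_abort("alphabet_size must lie in [2, 26]", "slcss_error_bad_config")
  }
  structure(list(m = as.integer(m), h = as.integer(h), delta = delta,
                 value_model = value_model,
                 alphabet_size = as.integer(alphabet_size),
                 int_range = as.integer(int_range),
                 displacement = as.integer(displacement), delta2 = delta2,
                 honest_noise = honest_noise, seed = seed),
            class = "synthetic_config")
}

# one draw of n data values under the config's value model
draw_values <- function(config, n) {
  switch(config$value_model,
         real = stats::runif(n),
         symbolic = sample(LETTERS[seq_len(config$alphabet_size)], n,
                           replace = TRUE),
         integer = sample(seq(config$int_range[1], config$int_range[2]), n,
                          replace = TRUE))
}

# replacement values: disjoint pool (shifted interval / lowercase letters /
# offset integers) unless honest_noise asks for the data distribution
draw_replacements <- function(config, n) {
  if (config$honest_noise) return(draw_values(config, n))
  switch(config$value_model,
         real = stats::runif(n, min = 2, max = 3),
         symbolic = sample(letters, n, replace = TRUE),
         integer = sample(seq(config$int_range[1], config$int_range[2]) +
                            1000L, n, replace = TRUE))
}

#' Generate a synthetic series pair with planted matches
#'
#' Builds `S` from the configured value model, then builds `T` row by row:
#' with probability `delta` the row is a planted copy of an `S` row (placed
#' at the same position, or jittered by up to `displacement` and repaired to
#' keep placements strictly increasing); otherwise the row is a replacement,
#' guaranteed unequal on variable 1 unless `honest_noise` is on.  Additional
#' variables of a planted row are copied with probability `delta2` each and
#' perturbed otherwise.  The planted trace is the strictly increasing record
#' of the surviving copies and lower-bounds what an unbounded-window search
#' can recover when values are duplicate-free.
#'
#' @param config a [synthetic_config()].
#' @return list with `S`, `T` (`multivariate_series` of length `m`) and
#'   `planted` (a [match_trace()]).
#' @examples
#' gp <- generate_pair(synthetic_config(m = 20, delta = 1, seed = 1))
#' length(gp$planted)  # 20: delta = 1 copies every row
#' @export
generate_pair <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed, {
    m <- config$m; h <- config$h; d <- config$displacement
    vars <- paste0("V", seq_len(h))
    S_cols <- stats::setNames(lapply(vars, function(v) draw_values(config, m)),
                              vars)
    planted_i <- which(stats::runif(m) < config$delta) - 1L  # 0-based

    # jittered target positions, repaired to stay strictly increasing in [0, m)
    q <- planted_i
    if (d > 0 && length(q)) {
      q <- q + sample(seq(-d, d), length(q), replace = TRUE)
      for (k in seq_along(q)) {
        lo <- if (k == 1) 0L else q[k - 1L] + 1L
        q[k] <- max(q[k], lo)
      }
      keep <- q <= m - 1L
      planted_i <- planted_i[keep]
      q <- q[keep]
    }

    T_cols <- stats::setNames(lapply(vars, function(v)
      draw_replacements(config, m)), vars)
    if (length(q)) {
      T_cols[[1]][q + 1L] <- S_cols[[1]][planted_i + 1L]
      if (h > 1) {
        for (v in vars[-1]) {
          copy <- stats::runif(length(q)) < config$delta2
          T_cols[[v]][q[copy] + 1L] <- S_cols[[v]][planted_i[copy] + 1L]
        }
      }
    }

    list(S = multivariate_series(S_cols, id = "synthetic_S"),
         T = multivariate_series(T_cols, id = "synthetic_T"),
         planted = match_trace(planted_i, q, sigma = Inf))
  })
}

#' Benchmark suite of synthetic configurations
#'
#' Deterministic desk-scale suites covering the three benchmark protocols:
#' constant length with growing dimensionality, constant dimensionality with
#' growing length, and one large pair.
#'
#' @param protocol `"constant_length"`, `"constant_dimension"` or `"large"`.
#' @param m,h,delta overrides for the fixed parameter and similarity level.
#' @param lengths,dimensions grids for the varying parameter.
#' @param seed base seed; configuration `k` uses `seed + k`.
#' @return list of [synthetic_config()]s.
#' @export
generate_benchmark_suite <- function(protocol = c("constant_length",
                                                  "constant_dimension",
                                                  "large"),
                                     m = 500, h = 3, delta = 0.5,
                                     lengths = c(100, 500, 1000, 5000),
                                     dimensions = 1:10, seed = 1L) {
  protocol <- match.arg(protocol)
  configs <- switch(protocol,
    constant_length = lapply(seq_along(dimensions), function(k)
      synthetic_config(m = m, h = dimensions[k], delta = delta,
                       seed = seed + k)),
    constant_dimension = lapply(seq_along(lengths), function(k)
      synthetic_config(m = lengths[k], h = h, delta = delta,
                       seed = seed + k)),
    large = list(synthetic_config(m = 12000, h = 1, delta = delta,
                                  seed = seed + 1L))
  )
  configs
}
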