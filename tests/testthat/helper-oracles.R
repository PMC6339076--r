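# Independent brute-force LCS oracle: enumerates index subsets of the shorter
# sequence in decreasing length and returns the first (longest) one that is a
# subsequence of the other.  Exponential, usable up to length ~12; shares no
# code with the DP or the windowed heuristic.

is_subseq <- function(sub, b) {
  p <- 0L
  for (x in sub) {
    w <- which(b == x)
    w <- w[w > p]
    if (length(w) == 0) return(FALSE)
    p <- w[1]
  }
  TRUE
}

oracle_lcs_length <- function(a, b) {
  if (length(a) > length(b)) {
    tmp <- a; a <- b; b <- tmp
  }
  m <- length(a)
  if (m == 0) return(0L)
  for (L in m:1) {
    for (idx in utils::combn(m, L, simplify = FALSE)) {
      if (is_subseq(a[idx], b)) return(L)
    }
  }
  0L
}
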