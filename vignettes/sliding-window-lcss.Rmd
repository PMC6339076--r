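---
title: "Sliding-window LCSS similarity: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sliding-window LCSS similarity: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slcss)
```

## The problem and the model

Two series are compared by the length of their longest common subsequence
(LCSS): the longest sequence obtainable from both by deleting elements while
preserving order.  Unlike Euclidean or warping distances, the LCSS is a
non-metric similarity and is insensitive to outliers — a wild reading costs
one potential match, nothing more.  The classical dynamic-programming (DP)
solution compares every element of one series with every element of the
other to fill an $(m+1)\times(n+1)$ table, which is exact but always costs
$\Theta(mn)$ time, even when the two series are nearly identical.

This package implements a windowed greedy heuristic for that problem.  One
*pass* scans $S$ left to right, holding a trace pointer $TP$ into $T$:

* element $S_i$ is compared against at most $\sigma$ candidate positions
  $T_{TP}, \ldots, T_{TP+\sigma-1}$ (clipped at the end of $T$);
* the first equal position $j$ becomes the match $(i, j)$ and $TP$ moves to
  $j + 1$;
* if the whole window fails, $TP$ stays put and only $i$ advances — a failed
  element never discards candidates for its successors.

Because a single unlucky early match can block later ones, the pass is
restarted from suffix starts $a = 0, 1, \ldots, M$ of $S$ and the longest
trace is kept (strict improvement only, so the earliest best start wins).
With the early-termination rule the restart loop also stops as soon as the
incumbent length reaches $M$.

For a multivariate series the heuristic is *anchor-then-filter*: the
windowed search runs on one anchor variable (the first column by default),
and its matched index pairs are then refined by requiring equality of every
remaining variable at those row pairs.  The surviving set is exactly
$\{(i,j) \in \text{trace} : \text{all requested variables equal}\}$, so
refinement is idempotent, order-invariant and monotone non-increasing —
properties the test suite asserts on randomized traces.

The reported similarity index is the final matched length divided by the
length of the shorter input (and 0 for empty input).  The normalization is
this package's definition; the length itself is the primitive quantity.

## Tunable parameters

* `sigma` (window width, positions; default 3): the maximum number of
  candidate positions of $T$ examined per element of $S$, counted from $TP$
  inclusive — so `sigma = 3` means "each element of $S$ is matched with at
  most three elements of $T$".  Small values suit slowly varying channels
  (air temperature from a field logger); large values suit strongly
  fluctuating series such as financial data.  `Inf` removes the bound.
* `max_start` / `start_fraction` (default half the length of $S$): the
  restart depth $M$.  Half-length is the package default; the fraction is a
  parameter because the appropriate depth is data-dependent, and an
  exhaustive search (`max_start = m`, `early_stop = FALSE`) is available
  when fidelity matters more than speed.
* `early_stop` (default on): stop restarting once the incumbent length
  reaches $M$.  Faithful to the restart loop's termination rule and cheap,
  but it can forfeit longer traces from later starts; the test suite checks
  that disabling it never shortens the result.
* `anchor` (default: first column): the variable the windowed search runs
  on.  The choice materially changes the result — anchoring on a noisy
  channel wastes the search — so it is exposed rather than hidden.
* `eq_spec(mode, epsilon)`: exact equality by default (what raw sensor
  readings and symbol sequences use).  Absolute tolerance
  $|a-b| \le \varepsilon$ is opt-in, per variable, for normalized or
  floating-point data.  Tolerance equality is not transitive; the DP result
  under tolerance is therefore flagged as not guaranteed optimal.

Greedy matching is **not monotone in `sigma`**: with $S = ABB$, $T = BBA$,
a window of 2 finds two matches while an unbounded window finds one (the
first $A$ consumes $T$'s last position and blocks everything after it).
The window is not merely an economy; it also regularizes the greedy choice.
Both behaviours are pinned by tests.

## Normalization

`normalize_minmax()` rescales a channel to $[0,1]$ by its extremes;
`normalize_pair()` applies it per variable with, by default, extremes pooled
over *both* series (joint-pair scope).  Pooling is the default because
per-series scaling destroys cross-series value identity — 35 °C in $S$ and
35 °C in $T$ would stop being equal — which exact matching depends on.
Normalization is off by default in the pipeline (`mlcss(normalize =
FALSE)`): raw integer-valued sensor readings match exactly without it, and
the worked examples in the README use raw values.  A constant channel maps
to all zeros rather than erroring, since constant sensor channels occur in
practice.

## Complexity, measured as comparisons

Wall-clock time is hardware-bound, so the package instruments the unit that
is not: evaluations of the equality predicate.  `comparison_count()` is
exact.  Two surrogates characterize the heuristic:

* best case — identical inputs cost exactly $m$ comparisons in one pass
  (every element matches at the first window position and the early stop
  fires), against the DP's unconditional $mn$;
* worst case — any run is bounded by $(M+1)\,m\,\sigma$ comparisons.

`run_benchmark()` reports both algorithms' counts (plus labelled,
hardware-dependent timings) over three synthetic protocols: constant length
with growing dimensionality, constant dimensionality with growing length,
and a single large pair (12,000 rows).  The test suite exercises the
protocols at reduced sizes (tens to hundreds of rows) — enough to pin the
counting behaviour, which is scale-free.

## The synthetic generator

`generate_pair()` plants controllable similarity: each row of $S$ appears
in $T$ with probability `delta` (optionally displaced by up to `d`
positions, with placements repaired to stay strictly increasing), and every
other row of $T$ is drawn from a replacement pool *disjoint* from the data
values, so it cannot accidentally match on the anchor variable.  The
planted trace is returned and is itself a strictly increasing, feasible
match trace.  Additional variables of a planted row are copied with
probability `delta2` each, which plants exactly the kind of cross-variable
disagreement (a humidity value differing at a matched temperature pair)
that refinement exists to remove.

Value models: continuous uniform draws (default), a symbolic alphabet
(DNA-like, default $k=4$), and an integer range (quantized sensor
readings).  The continuous default emulates real-valued sensor channels,
where duplicate values are measure-zero: each $S$ element then has exactly
one possible partner in $T$, the planted copy, and an unbounded-window
exhaustive search recovers the planted trace essentially exactly — the
parameter-recovery test (mean recovered length/$m$ within 0.05 of `delta`
at $m = 500$ over 200 seeds per level) verifies precisely this.  With the
symbolic model at small $k$, cross-matching between unrelated copies makes
greedy recovery much weaker; that is a property of greedy matching on
low-entropy alphabets, not a generator artifact, and it is why the recovery
condition is stated under the duplicate-free model.

What the generator does **not** emulate: autocorrelation, trends,
seasonality, drift, or sensor failure modes of real microclimate data.
Passing tests demonstrate the matching structure is handled correctly; they
say nothing about how informative an LCSS similarity index is for any
particular field deployment.

## Numerical and interface choices

* Coordinates are 0-based everywhere; a window is the closed range of
  positions $\{TP, \ldots, TP + \sigma - 1\}$.  One convention, stated
  once.
* Match positions are stored in original $S$ coordinates even for passes
  that start at a suffix, because refinement must look up other variables
  at those rows.
* The trace kept is the trace of the best pass; per-pass lengths are
  retained as diagnostics (`pass_lengths`), and the multivariate result
  records the per-stage history (e.g. temperature 8 → humidity 7).
* DP traceback tie-break: diagonal (match) first, then up, then left — one
  canonical, reproducible trace.  The DP table is materialized only on
  request; length-only calls use two rolling rows.
* A refined trace carries `sigma = Inf`: deleting interior pairs can widen
  the $j$-gaps beyond the original window, so the window-discipline
  invariant belongs to pass output only.
* Timestamps are opaque row labels.  Field-logger exports mix date formats
  and even non-monotone stamps; values, not timestamps, drive matching, so
  the reader keeps labels verbatim and only validates monotonicity for
  numeric or POSIX timestamps.
* Degenerate inputs: empty sequences yield an empty trace and length 0;
  `sigma < 1`, ragged columns, mismatched variable sets, and symbol/number
  mixing raise typed errors.
* Sequence pairs with duplicate-free values aside, ties inside a window are
  resolved by position: the *first* equal candidate wins.  This is what
  makes the greedy pass deterministic.

## Known limitations

* The heuristic is not optimal and its gap to the DP optimum is reported,
  not repaired; the suite asserts the one-sided bound
  $\text{heuristic} \le \text{DP}$ on thousands of random pairs and
  equality on identical inputs.
* The multivariate result depends on the anchor variable; the DP row-tuple
  reference (`dp_lcs_multivariate()`) bounds it from above but the heuristic
  may fall well short when the anchor is uninformative.
* The restart loop deletes prefixes of the first argument only; the
  comparison is asymmetric by construction (`auto_order = TRUE` swaps the
  shorter sequence into first position when symmetry of cost matters).
* Early stopping trades completeness for speed, and the default restart
  depth of half the series length is a heuristic; both are parameters, and
  the exhaustive setting is the reference configuration in the recovery
  tests.

## Problem sizes used by the test suite

Oracle-bound checks run on 1,000 random pairs of length ≤ 30; brute-force
DP validation enumerates subsequences at lengths ≤ 12 (200 cases);
parameter recovery uses 200 seeds at $m = 500$ per similarity level;
refinement algebra uses 500 random traces; benchmark-harness checks run at
tens of rows.  These sizes were chosen to exercise every code path and
statistical claim at desk scale while keeping the default check fast.
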