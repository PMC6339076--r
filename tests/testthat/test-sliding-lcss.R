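test_that("the univariate worked example reproduces trace and subsequence", {
  tr <- greedy_pass(worked_S(), worked_T(), start = 0, sigma = 3)
  expect_equal(paste(worked_S()[tr$pairs$i + 1], collapse = ""), "ABACDADB")
  expect_equal(tr$pairs$i, c(0L, 2L, 3L, 4L, 6L, 7L, 8L, 9L))
  expect_equal(tr$pairs$j, c(1L, 2L, 4L, 5L, 6L, 7L, 8L, 9L))
})

test_that("the sensor temperature columns give the known 8-pair trace", {
  tr <- greedy_pass(sensor_S()$columns$temperature,
                    sensor_T()$columns$temperature, sigma = 3)
  expect_equal(tr$pairs$i, c(0L, 2L, 3L, 4L, 6L, 7L, 8L, 9L))
  expect_equal(tr$pairs$j, c(1L, 2L, 4L, 5L, 6L, 7L, 8L, 9L))
})

test_that("degenerate inputs and bad parameters behave as documented", {
  expect_equal(length(greedy_pass(character(0), chars("ABC"), sigma = 3)), 0)
  expect_equal(length(greedy_pass(chars("ABC"), character(0), sigma = 3)), 0)
  expect_error(greedy_pass(chars("A"), chars("A"), sigma = 0),
               class = "slcss_error_bad_sigma")
  expect_error(greedy_pass(chars("A"), chars("A"), start = 5),
               class = "slcss_error_bad_start")
  # greedy can block itself: A consumes T's last position
  tr <- greedy_pass(chars("ABCD"), chars("BCDA"), sigma = 4)
  expect_equal(as.data.frame(tr), data.frame(i = 0L, j = 3L))
})

test_that("suffix restarts recover a longer trace from a later start", {
  r <- sliding_lcss(chars("ABCD"), chars("BCDA"), sigma = 4, max_start = 2,
                    early_stop = FALSE)
  expect_equal(r$length, 3L)
  expect_equal(r$best_start, 1L)
  expect_equal(r$pass_lengths, c(1L, 3L, 2L))
})

test_that("identical sequences: one pass, length m, exactly m comparisons", {
  set.seed(31)
  for (m in c(1, 5, 40)) {
    s <- rand_seq(m)
    r <- sliding_lcss(s, s, sigma = 3, early_stop = TRUE)
    expect_equal(r$length, m)
    expect_equal(length(r$pass_lengths), 1L)
    expect_equal(comparison_count(r), m)
  }
  expect_equal(comparison_count(sliding_lcss(character(0), chars("AB"))), 0)
})

test_that("every returned trace respects the window discipline", {
  set.seed(13)
  for (k in 1:40) {
    sig <- sample(c(1, 2, 3, 5), 1)
    r <- sliding_lcss(rand_seq(sample(1:25, 1)), rand_seq(sample(1:25, 1)),
                      sigma = sig, early_stop = FALSE)
    j <- r$best_trace$pairs$j
    i <- r$best_trace$pairs$i
    if (length(j) > 1) {
      expect_true(all(diff(j) <= sig))
      expect_true(all(diff(i) >= 1) && all(diff(j) >= 1))
    }
  }
})

test_that("window discipline nests upward; sigma monotonicity fails, by design", {
  set.seed(17)
  # a trace found under sigma is a valid trace under every wider window
  for (k in 1:40) {
    s <- rand_seq(sample(1:25, 1)); t <- rand_seq(sample(1:25, 1))
    sig <- sample(1:4, 1)
    tr <- greedy_pass(s, t, sigma = sig)
    j <- tr$pairs$j
    if (length(j) > 1) expect_true(all(diff(j) <= sig + 2))
    expect_silent(match_trace(tr$pairs$i, j, sigma = sig + 2))
  }
  # greedy matching is NOT monotone in sigma: a wide window lets an early
  # element consume a distant position and block later matches
  expect_equal(length(greedy_pass(chars("ABB"), chars("BBA"), sigma = 2)), 2)
  expect_equal(length(greedy_pass(chars("ABB"), chars("BBA"), sigma = Inf)), 1)
})

test_that("early stopping can only shorten the result, never lengthen it", {
  set.seed(19)
  for (k in 1:30) {
    s <- rand_seq(sample(1:30, 1)); t <- rand_seq(sample(1:30, 1))
    full <- sliding_lcss(s, t, sigma = 3, early_stop = FALSE)
    stopped <- sliding_lcss(s, t, sigma = 3, early_stop = TRUE)
    expect_gte(full$length, stopped$length)
  }
})

test_that("the heuristic never beats the dp optimum; ties on identity", {
  set.seed(23)
  for (k in 1:50) {
    s <- rand_seq(sample(0:20, 1), sample(2:6, 1))
    t <- if (k %% 5 == 0) s else rand_seq(sample(0:20, 1), sample(2:6, 1))
    opt <- dp_lcs(s, t, trace = FALSE)$length
    r <- sliding_lcss(s, t, sigma = sample(c(1, 3, length(t) + 1), 1),
                      early_stop = FALSE)
    expect_lte(r$length, opt)
    if (identical(s, t)) expect_equal(r$length, opt)
  }
})

test_that("comparison counts honour the (M+1) * m * sigma bound", {
  set.seed(29)
  for (k in 1:40) {
    s <- rand_seq(sample(1:30, 1)); t <- rand_seq(sample(1:30, 1))
    sig <- sample(1:4, 1)
    r <- sliding_lcss(s, t, sigma = sig, early_stop = FALSE)
    expect_lte(comparison_count(r),
               (r$parameters$max_start + 1) * length(s) * sig)
  }
})

test_that("auto_order scans the shorter sequence but reports it", {
  s <- chars("AB"); t <- chars("XAYBZ")
  r <- sliding_lcss(t, s, sigma = 5, auto_order = TRUE)
  expect_true(r$parameters$swapped)
  expect_equal(r$length, 2L)
})
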