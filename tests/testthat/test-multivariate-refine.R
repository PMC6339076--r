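test_that("humidity refinement deletes exactly the 82-vs-81 pair", {
  S <- sensor_S(); T <- sensor_T()
  stage1 <- greedy_pass(S$columns$temperature, T$columns$temperature,
                        sigma = 3)
  refined <- refine_trace(stage1, S, T, variables = "humidity")
  expect_equal(length(refined), 7L)
  dropped <- setdiff(paste(stage1$pairs$i, stage1$pairs$j),
                     paste(refined$pairs$i, refined$pairs$j))
  expect_equal(dropped, "8 8")
  expect_equal(S$columns$humidity[8 + 1], 82)
  expect_equal(T$columns$humidity[8 + 1], 81)
  # soil moisture agrees at all seven surviving pairs
  refined2 <- refine_trace(refined, S, T, variables = "soil_moisture")
  expect_equal(length(refined2), 7L)
})

test_that("zero-variable and all-disagreeing refinements hit the extremes", {
  S <- sensor_S(); T <- sensor_T()
  tr <- greedy_pass(S$columns$temperature, T$columns$temperature, sigma = 3)
  expect_identical(refine_trace(tr, S, T, variables = character(0)), tr)
  S2 <- multivariate_series(list(a = c(1, 2, 3), b = c(7, 7, 7)))
  T2 <- multivariate_series(list(a = c(1, 2, 3), b = c(8, 8, 8)))
  tr2 <- greedy_pass(S2$columns$a, T2$columns$a, sigma = 3)
  expect_equal(length(refine_trace(tr2, S2, T2)), 0L)
  expect_error(refine_trace(tr2, S2, T2, variables = "zzz"),
               class = "slcss_error_unknown_variable")
})

test_that("refinement is idempotent, order-invariant and non-increasing", {
  set.seed(37)
  for (k in 1:40) {
    m <- sample(5:30, 1)
    S <- multivariate_series(list(a = sample(1:4, m, TRUE),
                                  b = sample(1:3, m, TRUE),
                                  c = sample(1:3, m, TRUE)))
    T <- multivariate_series(list(a = sample(1:4, m, TRUE),
                                  b = sample(1:3, m, TRUE),
                                  c = sample(1:3, m, TRUE)))
    tr <- greedy_pass(S$columns$a, T$columns$a, sigma = sample(2:4, 1))
    r1 <- refine_trace(tr, S, T, variables = c("b", "c"))
    expect_lte(length(r1), length(tr))
    expect_equal(refine_trace(r1, S, T, variables = c("b", "c"))$pairs,
                 r1$pairs)
    r2 <- refine_trace(tr, S, T, variables = c("c", "b"))
    expect_equal(r1$pairs, r2$pairs)
    r3 <- refine_trace(refine_trace(tr, S, T, variables = "b"), S, T,
                       variables = "c")
    expect_equal(r1$pairs, r3$pairs)
  }
})

test_that("the full pipeline reports the 8 -> 7 stage history", {
  r <- mlcss(sensor_S(), sensor_T(), sigma = 3)
  expect_equal(r$anchor_length, 8L)
  expect_equal(r$length, 7L)
  expect_equal(unname(r$stage_lengths), c(8L, 7L, 7L))
  expect_equal(names(r$stage_lengths),
               c("temperature", "humidity", "soil_moisture"))
  expect_equal(similarity_index(r, 10, 10), 0.7)
})

test_that("pipeline identity and disjoint cases hit the extremes", {
  S <- sensor_S()
  expect_equal(mlcss(S, S, sigma = 3)$length, 10L)
  A <- multivariate_series(list(x = c(1, 2, 3), y = c(1, 1, 1)))
  B <- multivariate_series(list(x = c(7, 8, 9), y = c(1, 1, 1)))
  expect_equal(mlcss(A, B, sigma = 3)$length, 0L)
  expect_equal(similarity_index(mlcss(A, B), 3, 3), 0)
  expect_equal(similarity_index(mlcss(A, B), 0, 3), 0)
})

test_that("heuristic results are bounded by both dp references", {
  set.seed(41)
  for (k in 1:25) {
    m <- sample(5:25, 1)
    S <- multivariate_series(list(a = sample(1:4, m, TRUE),
                                  b = sample(1:3, m, TRUE)))
    T <- multivariate_series(list(a = sample(1:4, m, TRUE),
                                  b = sample(1:3, m, TRUE)))
    r <- mlcss(S, T, sigma = 3, early_stop = FALSE)
    opt1 <- dp_lcs(S$columns$a, T$columns$a, trace = FALSE)$length
    optm <- dp_lcs_multivariate(S, T, trace = FALSE)$length
    expect_lte(r$length, r$anchor_length)
    expect_lte(r$anchor_length, opt1)
    expect_lte(r$length, optm)
  }
})

test_that("the anchor variable is selectable and changes the search", {
  S <- sensor_S(); T <- sensor_T()
  r <- mlcss(S, T, sigma = 3, anchor = "humidity")
  expect_equal(names(r$stage_lengths)[1], "humidity")
  expect_error(mlcss(S, T, anchor = "zzz"),
               class = "slcss_error_unknown_variable")
})
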