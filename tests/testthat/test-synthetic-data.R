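test_that("delta = 1 copies every row; delta = 0 plants nothing", {
  gp <- generate_pair(synthetic_config(m = 30, h = 2, delta = 1, seed = 1))
  expect_equal(length(gp$planted), 30L)
  expect_identical(gp$S$columns, gp$T$columns)
  expect_equal(mlcss(gp$S, gp$T, sigma = 1)$length, 30L)

  gp0 <- generate_pair(synthetic_config(m = 30, delta = 0, seed = 2))
  expect_equal(length(gp0$planted), 0L)
  expect_equal(mlcss(gp0$S, gp0$T, sigma = 3)$length, 0L)
})

test_that("generation is reproducible and validates its configuration", {
  cfg <- synthetic_config(m = 40, h = 3, delta = 0.5, displacement = 2,
                          delta2 = 0.7, seed = 99)
  expect_identical(generate_pair(cfg), generate_pair(cfg))
  expect_error(synthetic_config(m = 10, displacement = 10),
               class = "slcss_error_bad_config")
  expect_error(synthetic_config(delta = 1.5), class = "slcss_error_bad_config")
  expect_error(synthetic_config(h = 0), class = "slcss_error_bad_config")
})

test_that("planted traces are valid and anchored to equal values", {
  for (seed in 1:5) {
    cfg <- synthetic_config(m = 60, h = 2, delta = 0.4, displacement = 3,
                            seed = seed)
    gp <- generate_pair(cfg)
    p <- gp$planted$pairs
    if (nrow(p) > 1) {
      expect_true(all(diff(p$i) > 0) && all(diff(p$j) > 0))
    }
    expect_true(all(gp$S$columns[[1]][p$i + 1] == gp$T$columns[[1]][p$j + 1]))
  }
})

test_that("planted count follows the binomial and is recoverable", {
  gp <- generate_pair(synthetic_config(m = 1000, h = 1, delta = 0.5,
                                       seed = 123))
  expect_lt(abs(length(gp$planted) - 500), 3 * sqrt(1000 * 0.25))
  r <- sliding_lcss(gp$S$columns[[1]], gp$T$columns[[1]], sigma = Inf,
                    max_start = 0)
  expect_gte(r$length, length(gp$planted))
})

test_that("delta2 plants cross-variable disagreements for refinement", {
  cfg <- synthetic_config(m = 80, h = 2, delta = 1, delta2 = 0, seed = 7)
  gp <- generate_pair(cfg)
  r <- mlcss(gp$S, gp$T, sigma = 1)
  expect_equal(r$anchor_length, 80L)
  expect_equal(r$length, 0L)  # second variable never copied

  cfg2 <- synthetic_config(m = 80, h = 2, delta = 1, delta2 = 0.5, seed = 8)
  r2 <- mlcss(generate_pair(cfg2)$S, generate_pair(cfg2)$T, sigma = 1)
  expect_lt(r2$length, 80L)
  expect_gt(r2$length, 0L)
})

test_that("symbolic and integer models use disjoint replacement pools", {
  gs <- generate_pair(synthetic_config(m = 50, delta = 0.5,
                                       value_model = "symbolic",
                                       alphabet_size = 4, seed = 3))
  p <- gs$planted$pairs
  non_planted <- setdiff(seq_len(50) - 1L, p$j)
  expect_true(all(gs$T$columns[[1]][non_planted + 1] %in% letters))
  expect_true(all(gs$S$columns[[1]] %in% LETTERS[1:4]))

  gi <- generate_pair(synthetic_config(m = 50, delta = 0.5,
                                       value_model = "integer", seed = 4))
  non_planted_i <- setdiff(seq_len(50) - 1L, gi$planted$pairs$j)
  expect_true(all(gi$T$columns[[1]][non_planted_i + 1] > 1000))
})

test_that("benchmark suites have the documented cardinalities", {
  expect_length(generate_benchmark_suite("constant_length"), 10L)
  expect_length(generate_benchmark_suite("constant_dimension"), 4L)
  large <- generate_benchmark_suite("large")
  expect_length(large, 1L)
  expect_equal(large[[1]]$m, 12000L)
  expect_equal(large[[1]]$h, 1L)
})
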