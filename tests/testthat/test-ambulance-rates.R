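test_that("survey aggregation conserves totals", {
  reg <- generate_registry(city_template(), seed = 1)
  svy <- generate_survey(reg, seed = 6)
  agg <- aggregate_survey(svy)
  expect_equal(sum(agg$n_total), nrow(svy))
  expect_equal(sum(agg$n_ambulance), sum(svy$used_ambulance))
  expect_true(all(agg$n_ambulance <= agg$n_total))

  empty <- aggregate_survey(tibble::tibble(neighborhood_id = character(),
                                           used_ambulance = integer()))
  expect_equal(nrow(empty), 0)

  one_area <- aggregate_survey(tibble::tibble(
    neighborhood_id = rep("z", 3), used_ambulance = c(1, 0, 0)))
  expect_equal(one_area$n_total, 3)
  expect_equal(one_area$n_ambulance, 1)
})

test_that("pooled rate is users over surveyed patients", {
  survey_scale <- tibble::tibble(neighborhood_id = "x",
                                 n_total = 1964, n_ambulance = 183)
  expect_equal(round(pooled_rate(survey_scale), 3), 0.093)
  expect_equal(pooled_rate(tibble::tibble(neighborhood_id = "x",
                                          n_total = 5, n_ambulance = 5)), 1)
  expect_equal(pooled_rate(tibble::tibble(neighborhood_id = c("a", "b"),
                                          n_total = c(2, 2),
                                          n_ambulance = c(1, 1))), 0.5)
  expect_error(pooled_rate(tibble::tibble(neighborhood_id = "x",
                                          n_total = 0, n_ambulance = 0)),
               "zero")
})

test_that("naive rate is the unweighted mean of proportions", {
  two <- tibble::tibble(neighborhood_id = c("a", "b"),
                        n_total = c(10, 10), n_ambulance = c(0, 2))
  expect_equal(naive_rate(two)$delta, 0.1)

  flat <- tibble::tibble(neighborhood_id = letters[1:5],
                         n_total = c(4, 8, 12, 16, 20),
                         n_ambulance = c(1, 2, 3, 4, 5))
  expect_equal(naive_rate(flat)$delta, 0.25)

  # 50-row random fixture against an element-wise loop oracle
  counts <- make_counts(50, seed = 13)
  oracle <- 0
  for (i in seq_len(nrow(counts))) {
    oracle <- oracle + counts$n_ambulance[i] / counts$n_total[i]
  }
  expect_equal(naive_rate(counts)$delta, oracle / nrow(counts))

  # zero-respondent rows are excluded, not averaged in
  with_zero <- dplyr::bind_rows(two, tibble::tibble(
    neighborhood_id = "c", n_total = 0L, n_ambulance = 0L))
  expect_equal(naive_rate(with_zero)$delta, 0.1)
  expect_error(naive_rate(tibble::tibble(neighborhood_id = "c",
                                         n_total = 0L, n_ambulance = 0L)),
               "no neighborhood")
})

test_that("weighted naive rate uses daytime population weights", {
  counts <- make_counts(20, seed = 21)
  reg_equal <- tiny_registry(20)
  expect_equal(weighted_naive_rate(counts, reg_equal)$delta,
               naive_rate(counts)$delta)

  single <- counts[1, ]
  expect_equal(weighted_naive_rate(single, reg_equal)$delta,
               single$n_ambulance / single$n_total)

  reg_var <- tiny_registry(20, pop_night = seq(100, 2000, by = 100))
  oracle <- sum((reg_var$pop_day / sum(reg_var$pop_day)) *
                  counts$n_ambulance / counts$n_total)
  expect_equal(weighted_naive_rate(counts, reg_var)$delta, oracle)

  expect_error(weighted_naive_rate(counts, reg_var[1:5, ]),
               "lacks populations")
})

test_that("degenerate observed proportions collapse the bootstrap", {
  zeros <- tibble::tibble(neighborhood_id = letters[1:4],
                          n_total = c(5, 8, 3, 9),
                          n_ambulance = 0L)
  mc0 <- monte_carlo_rate(zeros, n_replicates = 100, seed = 1)
  expect_equal(mc0$delta, 0)
  expect_equal(mc0$ci_low, 0)
  expect_equal(mc0$ci_high, 0)

  ones <- dplyr::mutate(zeros, n_ambulance = n_total)
  expect_equal(monte_carlo_rate(ones, n_replicates = 100, seed = 1)$delta, 1)

  expect_error(monte_carlo_rate(zeros, n_replicates = 1), "at least 2")
})

test_that("the binomial bootstrap is centred on the naive estimate", {
  counts <- make_counts(40, n_range = c(30, 60), rate = 0.093, seed = 31)
  mc <- monte_carlo_rate(counts, n_replicates = 10000, seed = 32)
  se <- sd(mc$replicate_means) / sqrt(mc$n_replicates)
  expect_lt(abs(mc$delta - naive_rate(counts)$delta), 3 * se)
  expect_length(mc$replicate_means, 10000)
  expect_true(mc$ci_low <= mc$delta && mc$delta <= mc$ci_high)
})

test_that("replicate means are identical under the same seed", {
  counts <- make_counts(15, seed = 41)
  a <- monte_carlo_rate(counts, n_replicates = 500, seed = 99)
  b <- monte_carlo_rate(counts, n_replicates = 500, seed = 99)
  c <- monte_carlo_rate(counts, n_replicates = 500, seed = 100)
  expect_identical(a$replicate_means, b$replicate_means)
  expect_false(identical(a$replicate_means, c$replicate_means))
})

test_that("all three estimators stay within [0, 1]", {
  for (seed in 1:8) {
    counts <- make_counts(12, n_range = c(1, 10),
                          rate = runif(1, 0, 1), seed = seed)
    reg <- tiny_registry(12, pop_night = sample(100:5000, 12))
    deltas <- c(naive_rate(counts)$delta,
                weighted_naive_rate(counts, reg)$delta,
                monte_carlo_rate(counts, 200, seed = seed)$delta)
    expect_true(all(deltas >= 0 & deltas <= 1))
  }
})

test_that("the bootstrap CI covers the naive value at close to nominal rate", {
  reg <- tiny_registry(30, pop_night = rep(2000, 30))
  n_surveys <- 200
  covered <- vapply(seq_len(n_surveys), function(s) {
    counts <- make_counts(30, n_range = c(20, 40), rate = 0.093,
                          seed = 5000 + s)
    mc <- monte_carlo_rate(counts, n_replicates = 400, seed = 6000 + s)
    ref <- naive_rate(counts)$delta  # the bootstrap mean's true centre
    mc$ci_low <= ref && ref <= mc$ci_high
  }, logical(1))
  expect_lt(abs(mean(covered) - 0.95), 0.05)
})

test_that("the one-sample t-test matches its closed form", {
  x <- withr::with_seed(7, rnorm(100, mean = 0.075, sd = 0.002))
  est <- fake_simulation_estimate(x)
  cmp <- compare_to_reference(est, 0.074, "naive")
  t_manual <- (mean(x) - 0.074) / (sd(x) / sqrt(length(x)))
  p_manual <- 2 * pt(-abs(t_manual), df = length(x) - 1)
  expect_equal(cmp$t_statistic, t_manual)
  expect_equal(cmp$p_value, p_manual)
  expect_equal(cmp$df, 99)
})

test_that("t-test behaviour at symmetric and far-shifted replicates", {
  sym <- fake_simulation_estimate(c(0.07, 0.08, 0.09, 0.10, 0.11))
  cmp <- compare_to_reference(sym, 0.09)
  expect_equal(cmp$t_statistic, 0)
  expect_equal(cmp$p_value, 1)

  x <- withr::with_seed(8, rnorm(200, mean = 0.08, sd = 0.001))
  shifted <- fake_simulation_estimate(x)
  far <- compare_to_reference(shifted, 0.08 - 10 * 0.001)
  expect_lt(far$p_value, 0.001)

  flat <- fake_simulation_estimate(rep(0.05, 10))
  expect_error(compare_to_reference(flat, 0.05), "degenerate")
  expect_error(compare_to_reference(naive_rate(make_counts(5)), 0.05),
               "replicate means")
})
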