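eps_paper <- list(eps_day = 0.625, eps_night = 0.375)

test_that("per-neighborhood demand is the four-factor product", {
  reg <- tibble::tibble(id = "x", pop_day = 1000, pop_night = 800)
  out <- neighborhood_demand(reg, eps_paper, lam = 0.1, delta = 0.1)
  expect_equal(out$day_need, 6.25)
  expect_equal(out$night_need, 3)
  expect_equal(out$total_need, 9.25)

  none <- neighborhood_demand(reg, eps_paper, lam = 0.1, delta = 0)
  expect_equal(none$day_need, 0)
  expect_equal(none$night_need, 0)

  expect_error(neighborhood_demand(reg, eps_paper, lam = -1, delta = 0.1),
               "nonnegative")
})

test_that("demand totals equal a term-by-term summation oracle", {
  reg <- withr::with_seed(3, tibble::tibble(
    id = sprintf("r%02d", 1:10),
    pop_day = sample(500:5000, 10),
    pop_night = sample(500:5000, 10)))
  delta <- withr::with_seed(4, runif(10, 0, 0.2))
  out <- neighborhood_demand(reg, eps_paper, lam = 0.17, delta = delta)
  oracle_day <- 0
  oracle_night <- 0
  for (i in 1:10) {
    oracle_day <- oracle_day + reg$pop_day[i] * 0.625 * 0.17 * delta[i]
    oracle_night <- oracle_night + reg$pop_night[i] * 0.375 * 0.17 * delta[i]
  }
  agg <- aggregate_demand(out)
  expect_equal(agg$day_total_raw, oracle_day)
  expect_equal(agg$night_total_raw, oracle_night)
  expect_equal(agg$ambulance_total_raw, oracle_day + oracle_night)
})

test_that("aggregates are additive before rounding and round half-up", {
  # period totals printed at the city scale must sum exactly
  rows <- tibble::tibble(night_need = c(20000, 9203), day_need = c(50000, 3871))
  agg <- aggregate_demand(rows)
  expect_equal(agg$night_total, 29203)
  expect_equal(agg$day_total, 53871)
  expect_equal(agg$ambulance_total, 83074)

  rows2 <- tibble::tibble(night_need = 58402, day_need = 107751)
  expect_equal(aggregate_demand(rows2)$ambulance_total, 166153)

  single <- tibble::tibble(night_need = 10.5, day_need = 2.5)
  agg3 <- aggregate_demand(single)
  expect_equal(agg3$night_total, 11)  # half-up, not banker's rounding
  expect_equal(agg3$ambulance_total, 13)
})

test_that("ambulance totals convert to emergency-care need by the usage rate", {
  expect_equal(emergency_care_total(83074, 0.093), 893269)
  expect_equal(emergency_care_total(240911, 0.093), 2590441)
  expect_equal(emergency_care_total(12345, 1), 12345)
  expect_error(emergency_care_total(100, 0), "0, 1")
})

test_that("scenario table reproduces the closed-form city aggregate", {
  reg <- generate_registry(city_template(), seed = 17)
  sc <- estimate_per_capita_scenarios(jakarta_ed_summary())
  est <- list(fake_simulation_estimate(rep(c(0.074, 0.0741), 50)))
  est[[1]]$method <- "naive"
  est[[1]]$delta <- 0.07406
  tab <- build_scenario_table(reg, eps_paper, sc, est,
                              usage_rate = 0.093, use_rounded_rates = TRUE)
  low <- tab[tab$rate_label == "low", ]
  closed_form <- (10.5e6 * 0.375 + 11.6e6 * 0.625) * 0.10 * 0.07406
  expect_equal(low$ambulance_total_raw, closed_form, tolerance = 1e-9)
  expect_equal(low$emergency_care_total,
               round_half_up(low$ambulance_total_raw / 0.093))
})

test_that("demand is homogeneous of degree one in lambda and delta", {
  reg <- generate_registry(city_template(), seed = 19)
  base <- neighborhood_demand(reg, eps_paper, lam = 0.1, delta = 0.074)
  lam2 <- neighborhood_demand(reg, eps_paper, lam = 0.2, delta = 0.074)
  del2 <- neighborhood_demand(reg, eps_paper, lam = 0.1, delta = 0.148)
  expect_equal(lam2$total_need, 2 * base$total_need)
  expect_equal(del2$total_need, 2 * base$total_need)
  expect_equal(aggregate_demand(lam2)$ambulance_total_raw,
               2 * aggregate_demand(base)$ambulance_total_raw)
})

test_that("a one-neighborhood city yields its own demand as the table", {
  reg <- tibble::tibble(id = "solo", pop_day = 1000, pop_night = 800)
  sc <- tibble::tibble(label = "mid", quantile = 1, implied_total_visits = 1,
                       lam = 0.1, lam_rounded = 0.1)
  est <- list(structure(list(method = "naive", delta = 0.1,
                             n_neighborhoods = 1, ci_low = NA_real_,
                             ci_high = NA_real_, replicate_means = NULL,
                             n_replicates = NA_integer_, seed = NA_integer_),
                        class = "ambulance_rate_estimate"))
  tab <- build_scenario_table(reg, eps_paper, sc, est, usage_rate = 0.5)
  row <- neighborhood_demand(reg, eps_paper, 0.1, 0.1)
  expect_equal(tab$night_total_raw, row$night_need)
  expect_equal(tab$day_total_raw, row$day_need)
  expect_equal(nrow(tab), 1)
})

test_that("the full scenario table satisfies its identities", {
  reg <- generate_registry(city_template(), seed = 23)
  svy <- generate_survey(reg, seed = 24)
  counts <- aggregate_survey(svy)
  sc <- estimate_per_capita_scenarios(jakarta_ed_summary())
  ests <- list(naive_rate(counts),
               weighted_naive_rate(counts, reg),
               monte_carlo_rate(counts, 500, seed = 25))
  out <- build_scenario_table(reg, eps_paper, sc, ests, usage_rate = 0.093,
                              detail = TRUE)
  expect_equal(nrow(out$summary), 9)
  # additivity: day + night = total, exactly before rounding
  expect_equal(out$summary$night_total_raw + out$summary$day_total_raw,
               out$summary$ambulance_total_raw)
  # aggregate equals the per-neighborhood sum for each scenario
  by_hand <- out$by_neighborhood |>
    dplyr::group_by(method, rate_label) |>
    dplyr::summarise(total = sum(total_need), .groups = "drop")
  joined <- dplyr::left_join(out$summary, by_hand,
                             by = c("method", "rate_label"))
  expect_equal(joined$ambulance_total_raw, joined$total)
  # conversion identity returns the ambulance total to within rounding
  expect_true(all(abs(out$summary$emergency_care_total * 0.093 -
                        out$summary$ambulance_total_raw) <= 1))
})

test_that("study-scale rates place ambulance totals in the published band", {
  reg <- generate_registry(city_template(), seed = 29)
  sc <- estimate_per_capita_scenarios(jakarta_ed_summary())
  make_est <- function(method, delta) {
    structure(list(method = method, delta = delta, n_neighborhoods = 261,
                   ci_low = NA_real_, ci_high = NA_real_,
                   replicate_means = NULL, n_replicates = NA_integer_,
                   seed = NA_integer_),
              class = "ambulance_rate_estimate")
  }
  ests <- list(make_est("naive", 0.07406),
               make_est("weighted_naive", 0.07403),
               make_est("simulation", 0.07391))
  tab <- build_scenario_table(reg, eps_paper, sc, ests,
                              usage_rate = 0.093, use_rounded_rates = TRUE)
  expect_true(all(tab$ambulance_total >= 82000 - 2000 &
                    tab$ambulance_total <= 242000 + 2000))
  expect_true(all(tab$emergency_care_total >= 0.88e6 &
                    tab$emergency_care_total <= 2.62e6))
})

test_that("missing estimates are a configuration error", {
  reg <- tiny_registry(2)
  sc <- estimate_per_capita_scenarios(jakarta_ed_summary())
  expect_error(build_scenario_table(reg, eps_paper, sc, list()),
               "at least one")
  expect_error(build_scenario_table(reg, eps_paper, sc, list(delta = 0.07)),
               "ambulance_rate_estimate")
})
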