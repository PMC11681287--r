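#' Expected annual ambulance needs per neighborhood
#'
#' For each neighborhood the expected annual number of ED arrivals by
#' ambulance in a period is `population x period probability x per-capita ED
#' rate x ambulance-use rate`:
#' `day_need = pop_day * eps_day * lam * delta` and
#' `night_need = pop_night * eps_night * lam * delta`. Full precision is
#' retained; rounding happens only when aggregates are reported.
#'
#' @param registry Registry tibble with `id`, `pop_day`, `pop_night`.
#' @param eps A `period_probs` object from
#'   [estimate_period_probabilities()], or a list with `eps_day`/`eps_night`.
#' @param lam Per-capita annual ED visit rate (scalar).
#' @param delta Ambulance-use rate: a scalar broadcast to every area, or a
#'   vector/named vector of per-neighborhood rates.
#' @return The registry rows with `night_need`, `day_need`, `total_need`.
#' @export
#' @examples
#' reg <- tibble::tibble(id = "x", pop_day = 1000, pop_night = 800)
#' eps <- list(eps_day = 0.625, eps_night = 0.375)
#' neighborhood_demand(reg, eps, lam = 0.1, delta = 0.1)
neighborhood_demand <- function(registry, eps, lam, delta) {
  check_columns(registry, c("id", "pop_day", "pop_night"), "`registry`")
  if (!is.list(eps) || is.null(eps$eps_day) || is.null(eps$eps_night)) {
    stop("`eps` must provide `eps_day` and `eps_night`", call. = FALSE)
  }
  if (lam < 0 || any(delta < 0) || eps$eps_day < 0 || eps$eps_night < 0) {
    stop("rates and probabilities must be nonnegative", call. = FALSE)
  }
  d <- if (length(delta) == 1) {
    rep(delta, nrow(registry))
  } else if (!is.null(names(delta))) {
    missing <- setdiff(registry$id, names(delta))
    if (length(missing) > 0) {
      stop("`delta` lacks entries for neighborhood(s): ",
           paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
    }
    unname(delta[registry$id])
  } else {
    if (length(delta) != nrow(registry)) {
      stop("unnamed `delta` vector must match the registry length",
           call. = FALSE)
    }
    delta
  }
  registry |>
    dplyr::mutate(
      night_need = .data$pop_night * eps$eps_night * lam * d,
      day_need = .data$pop_day * eps$eps_day * lam * d,
      total_need = .data$night_need + .data$day_need
    )
}

#' Aggregate per-neighborhood demand to city totals
#'
#' Sums the per-neighborhood period needs and reports them as integers by
#' half-up rounding of the aggregates (never of per-row values, which would
#' break additivity). The unrounded sums are kept alongside.
#'
#' @param rows Output of [neighborhood_demand()].
#' @return One-row tibble with `night_total`, `day_total`, `ambulance_total`
#'   (half-up rounded) and their `_raw` unrounded counterparts.
#' @export
aggregate_demand <- function(rows) {
  check_columns(rows, c("night_need", "day_need"), "`rows`")
  if (nrow(rows) == 0) {
    stop("`rows` must be nonempty", call. = FALSE)
  }
  night <- sum(rows$night_need)
  day <- sum(rows$day_need)
  tibble::tibble(
    night_total = round_half_up(night),
    day_total = round_half_up(day),
    ambulance_total = round_half_up(night + day),
    night_total_raw = night,
    day_total_raw = day,
    ambulance_total_raw = night + day
  )
}

#' Convert ambulance needs to total emergency-care need
#'
#' If only a fraction `usage_rate` of ED attenders arrive by ambulance, the
#' total annual emergency-care need implied by an ambulance total is
#' `ambulance_total / usage_rate`, half-up rounded for reporting.
#'
#' @param ambulance_total Annual ambulance needs (visits/year).
#' @param usage_rate Pooled ambulance-usage rate in (0, 1] (default 0.093).
#' @return Total annual ED visits implied (integer-valued).
#' @export
#' @examples
#' emergency_care_total(83074)  # 893,269
emergency_care_total <- function(ambulance_total, usage_rate = 0.093) {
  if (!is.finite(usage_rate) || usage_rate <= 0 || usage_rate > 1) {
    stop("`usage_rate` must lie in (0, 1]", call. = FALSE)
  }
  if (any(ambulance_total < 0)) {
    stop("`ambulance_total` must be nonnegative", call. = FALSE)
  }
  round_half_up(ambulance_total / usage_rate)
}

#' Build the scenario demand table
#'
#' Crosses the per-capita rate scenarios (low/mid/high) with the ambulance
#' rate estimators (naive, weighted naive, simulation) and computes, for each
#' combination, the aggregate nighttime, daytime and total annual ambulance
#' needs plus the implied total emergency-care need (always converted with
#' the pooled survey usage rate, not the estimator's own rate).
#'
#' @param registry Registry tibble with `id`, `pop_day`, `pop_night`.
#' @param eps Period probabilities (see [neighborhood_demand()]).
#' @param scenarios Tibble from [estimate_per_capita_scenarios()].
#' @param rate_estimates List of `ambulance_rate_estimate` objects (one per
#'   method).
#' @param usage_rate Pooled ambulance-usage rate for the emergency-care
#'   conversion (default 0.093).
#' @param use_rounded_rates If `TRUE`, demand uses the two-decimal rounded
#'   per-capita rates (matching published report labels); the default uses
#'   the unrounded rates.
#' @param detail If `TRUE`, also return the per-neighborhood rows for every
#'   scenario-method combination.
#' @return A tibble with one row per scenario x method: `method`,
#'   `rate_label`, `lam`, `delta`, `night_total`, `day_total`,
#'   `ambulance_total`, `emergency_care_total` (plus `_raw` columns). With
#'   `detail = TRUE`, a list with elements `summary` and `by_neighborhood`.
#' @export
build_scenario_table <- function(registry, eps, scenarios, rate_estimates,
                                 usage_rate = 0.093,
                                 use_rounded_rates = FALSE,
                                 detail = FALSE) {
  check_columns(scenarios, c("label", "lam", "lam_rounded"), "`scenarios`")
  if (length(rate_estimates) == 0) {
    stop("at least one rate estimate is required", call. = FALSE)
  }
  bad <- !vapply(rate_estimates, inherits, logical(1),
                 "ambulance_rate_estimate")
  if (any(bad)) {
    stop("`rate_estimates` must be ambulance_rate_estimate objects",
         call. = FALSE)
  }
  grid <- tidyr::expand_grid(
    scenario_idx = seq_len(nrow(scenarios)),
    method_idx = seq_along(rate_estimates)
  )
  per_combo <- purrr::pmap(grid, function(scenario_idx, method_idx) {
    sc <- scenarios[scenario_idx, ]
    est <- rate_estimates[[method_idx]]
    lam <- if (use_rounded_rates) sc$lam_rounded else sc$lam
    rows <- neighborhood_demand(registry, eps, lam = lam, delta = est$delta)
    agg <- aggregate_demand(rows)
    list(
      summary = dplyr::bind_cols(
        tibble::tibble(method = est$method, rate_label = sc$label,
                       lam = lam, delta = est$delta),
        agg,
        tibble::tibble(
          emergency_care_total = emergency_care_total(agg$ambulance_total_raw,
                                                      usage_rate)
        )
      ),
      rows = dplyr::mutate(rows, method = est$method, rate_label = sc$label,
                           .before = 1)
    )
  })
  summary <- purrr::map_dfr(per_combo, "summary")
  if (!detail) {
    return(summary)
  }
  list(summary = summary,
       by_neighborhood = purrr::map_dfr(per_combo, "rows"))
}
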