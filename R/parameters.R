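#' Commuter-adjust a registry into day and night populations
#'
#' Fills (or refreshes) the `pop_day` column: each municipality's signed net
#' commuter inflow is distributed over its neighborhoods proportionally to
#' nighttime population, with largest-remainder correction so the daytime
#' total equals the nighttime total plus the summed inflows exactly.
#'
#' @param registry Tibble with `id`, `municipality`, `pop_night`.
#' @param municipal_inflows Either a named numeric vector of net inflows
#'   (persons, signed) keyed by municipality, or a tibble with columns
#'   `municipality` and `net_inflow`. Municipalities absent from the table
#'   get zero inflow; an inflow for a municipality not in the registry is an
#'   error.
#' @return The registry with `pop_day = pop_night + allocated inflow`.
#' @export
#' @examples
#' reg <- tibble::tibble(id = c("a", "b"), municipality = "M",
#'                       pop_night = c(300, 100))
#' split_day_night_population(reg, c(M = -100))$pop_day  # 225, 75
split_day_night_population <- function(registry, municipal_inflows) {
  check_columns(registry, c("id", "municipality", "pop_night"), "`registry`")
  if (any(registry$pop_night <= 0)) {
    stop("all nighttime populations must be positive", call. = FALSE)
  }
  if (is.data.frame(municipal_inflows)) {
    check_columns(municipal_inflows, c("municipality", "net_inflow"),
                  "`municipal_inflows`")
    inflows <- stats::setNames(municipal_inflows$net_inflow,
                               municipal_inflows$municipality)
  } else {
    inflows <- municipal_inflows
  }
  unknown <- setdiff(names(inflows), unique(registry$municipality))
  if (length(unknown) > 0) {
    stop("inflow given for municipality not in the registry: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  registry |>
    dplyr::group_by(.data$municipality) |>
    dplyr::mutate(
      pop_day = .data$pop_night + allocate_integer(
        dplyr::coalesce(inflows[dplyr::cur_group()$municipality][[1]], 0),
        .data$pop_night
      )
    ) |>
    dplyr::ungroup()
}

#' Estimate day/night emergency probabilities from a survey
#'
#' The probability that an emergency falls in each period is the observed
#' share of survey records in that period. Records carry either a `period`
#' column (`"day"`/`"night"`) or an `arrival_time` column; times in
#' \[06:00, 18:00) count as day and the rest as night (half-open intervals,
#' so 06:00:00 exactly is day and 18:00:00 exactly is night).
#'
#' @param survey Tibble with a `period` column, or an `arrival_time` column
#'   of `POSIXct` times or `"HH:MM"`/`"HH:MM:SS"` strings.
#' @return An object of class `period_probs` with fields `eps_day`,
#'   `eps_night`, `n_day`, `n_night`.
#' @export
#' @examples
#' svy <- tibble::tibble(period = rep(c("day", "night"), c(1228, 736)))
#' estimate_period_probabilities(svy)
estimate_period_probabilities <- function(survey) {
  if (is.null(survey) || nrow(survey) == 0) {
    stop("`survey` must contain at least one record", call. = FALSE)
  }
  if ("period" %in% names(survey)) {
    period <- survey$period
    bad <- setdiff(unique(period), c("day", "night"))
    if (length(bad) > 0) {
      stop("`period` values must be \"day\" or \"night\"; found: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  } else if ("arrival_time" %in% names(survey)) {
    hour <- arrival_hour(survey$arrival_time)
    period <- ifelse(hour >= 6 & hour < 18, "day", "night")
  } else {
    stop("`survey` needs a `period` or `arrival_time` column", call. = FALSE)
  }
  n_day <- sum(period == "day")
  n_night <- sum(period == "night")
  structure(
    list(eps_day = n_day / (n_day + n_night),
         eps_night = n_night / (n_day + n_night),
         n_day = n_day, n_night = n_night),
    class = "period_probs"
  )
}

# fractional hour of day from POSIXct or "HH:MM[:SS]" strings
arrival_hour <- function(x) {
  if (inherits(x, "POSIXt")) {
    lt <- as.POSIXlt(x)
    return(lt$hour + lt$min / 60 + lt$sec / 3600)
  }
  parts <- strsplit(as.character(x), ":", fixed = TRUE)
  vapply(parts, function(p) {
    p <- as.numeric(p)
    if (any(is.na(p)) || length(p) < 2) {
      stop("unparseable arrival_time; use POSIXct or \"HH:MM[:SS]\"",
           call. = FALSE)
    }
    p[1] + p[2] / 60 + (if (length(p) >= 3) p[3] / 3600 else 0)
  }, numeric(1))
}

#' @export
print.period_probs <- function(x, ...) {
  cat(sprintf("<period_probs> day %.3f (n=%d) | night %.3f (n=%d)\n",
              x$eps_day, x$n_day, x$eps_night, x$n_night))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.period_probs <- function(x, ...) {
  tibble::tibble(period = c("day", "night"),
                 n = c(x$n_day, x$n_night),
                 probability = c(x$eps_day, x$eps_night))
}

#' Per-capita ED visit rate scenarios from a hospital sample
#'
#' Scales the sample's quartiles (Q1, median, Q3) up to the full set of
#' ED-equipped hospitals to get low/mid/high annual city-wide ED visit
#' totals, then divides by the resident population for per-capita rates.
#' Both the unrounded rate (used in demand arithmetic by default) and the
#' two-decimal rounded rate (used for report labels) are returned.
#'
#' @param hospitals A [hospital_volume_sample()].
#' @param n_hospitals_with_ed Number of ED-equipped hospitals in the city
#'   (default 86).
#' @param population Resident population used as the rate denominator
#'   (default 10.5 million).
#' @return A tibble with columns `label` (`low`/`mid`/`high`), `quantile`,
#'   `implied_total_visits`, `lam`, `lam_rounded`.
#' @export
#' @examples
#' estimate_per_capita_scenarios(jakarta_ed_summary())
estimate_per_capita_scenarios <- function(hospitals,
                                          n_hospitals_with_ed = 86,
                                          population = 10.5e6) {
  stopifnot(inherits(hospitals, "hospital_volume_sample"))
  if (!is.finite(population) || population <= 0) {
    stop("`population` must be positive", call. = FALSE)
  }
  if (n_hospitals_with_ed < 1) {
    stop("`n_hospitals_with_ed` must be at least 1", call. = FALSE)
  }
  s <- hospitals$summary
  q <- c(low = s$q1, mid = s$median, high = s$q3)
  tibble::tibble(
    label = names(q),
    quantile = unname(q),
    implied_total_visits = unname(q) * n_hospitals_with_ed,
    lam = unname(q) * n_hospitals_with_ed / population,
    lam_rounded = round_half_up(unname(q) * n_hospitals_with_ed / population * 100) / 100
  )
}
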