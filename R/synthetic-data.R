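#' City template for the synthetic-data generator
#'
#' Describes the administrative skeleton of the study region: municipalities,
#' districts per municipality, neighborhoods per municipality, the baseline
#' (nighttime) population, and the signed net commuter inflow each
#' municipality gains during the day. The default mirrors mainland Jakarta:
#' 5 municipalities, 42 districts, 261 neighborhoods, 10.5 million residents,
#' and a net daytime commuter inflow of 1.1 million concentrated in the
#' Central and South municipalities.
#'
#' @param municipalities Character vector of municipality names.
#' @param districts_per_municipality Integer vector, districts in each
#'   municipality (same order as `municipalities`).
#' @param neighborhoods_per_municipality Integer vector, neighborhoods in each
#'   municipality; they are spread as evenly as possible over that
#'   municipality's districts.
#' @param base_population Total nighttime population (persons).
#' @param commuter_net_inflow Named numeric vector of signed net daytime
#'   commuter inflows (persons), one entry per municipality.
#' @return An object of class `city_template`.
#' @export
#' @examples
#' tpl <- city_template()
#' tpl$total_neighborhoods
city_template <- function(municipalities = c("Central", "North", "West",
                                             "South", "East"),
                          districts_per_municipality = c(8, 6, 8, 10, 10),
                          neighborhoods_per_municipality = c(44, 31, 56, 65, 65),
                          base_population = 10.5e6,
                          commuter_net_inflow = c(Central = 524000,
                                                  North = 40000,
                                                  West = 60000,
                                                  South = 418000,
                                                  East = 58000)) {
  n_mun <- length(municipalities)
  if (length(districts_per_municipality) != n_mun ||
      length(neighborhoods_per_municipality) != n_mun) {
    stop("districts and neighborhood counts must match the number of municipalities",
         call. = FALSE)
  }
  if (!is.finite(base_population) || base_population <= 0) {
    stop("`base_population` must be positive", call. = FALSE)
  }
  if (any(districts_per_municipality < 1) ||
      any(neighborhoods_per_municipality < 1) ||
      any(neighborhoods_per_municipality < districts_per_municipality)) {
    stop("each municipality needs at least one district and at least one neighborhood per district",
         call. = FALSE)
  }
  if (is.null(names(commuter_net_inflow))) {
    names(commuter_net_inflow) <- municipalities[seq_along(commuter_net_inflow)]
  }
  unknown <- setdiff(names(commuter_net_inflow), municipalities)
  if (length(unknown) > 0) {
    stop("commuter inflow given for unknown municipality: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  # neighborhoods spread as evenly as possible over each municipality's districts
  nbhd_per_district <- purrr::map2(
    neighborhoods_per_municipality, districts_per_municipality,
    function(n, d) allocate_integer(n, rep(1, d))
  )
  structure(
    list(
      municipalities = municipalities,
      districts_per_municipality = as.integer(districts_per_municipality),
      neighborhoods_per_district = nbhd_per_district,
      total_districts = sum(districts_per_municipality),
      total_neighborhoods = sum(neighborhoods_per_municipality),
      base_population = base_population,
      commuter_net_inflow = commuter_net_inflow
    ),
    class = "city_template"
  )
}

#' @export
print.city_template <- function(x, ...) {
  cat("<city_template>\n")
  cat("  municipalities:", length(x$municipalities),
      "| districts:", x$total_districts,
      "| neighborhoods:", x$total_neighborhoods, "\n")
  cat("  base population:", format(x$base_population, big.mark = ","),
      "| net commuter inflow:",
      format(sum(x$commuter_net_inflow), big.mark = ","), "\n")
  invisible(x)
}

#' Generate a synthetic neighborhood registry
#'
#' Draws per-neighborhood nighttime populations and commuter-adjusted daytime
#' populations for a city template. Population mass is assigned to
#' municipalities and districts proportionally to their neighborhood counts;
#' within a district, neighborhood shares follow a symmetric Dirichlet law
#' (concentration `concentration`), keeping areas of a district comparable in
#' size. Integerisation uses largest-remainder allocation so nighttime
#' populations sum exactly to `template$base_population` and daytime
#' populations sum exactly to the base plus total net inflow.
#'
#' @param template A [city_template()].
#' @param seed Integer seed; identical seeds give identical registries.
#' @param concentration Dirichlet concentration for within-district shares.
#'   Larger values make neighborhoods within a district more similar.
#' @return A tibble with columns `id`, `district`, `municipality`,
#'   `pop_night`, `pop_day`.
#' @export
#' @examples
#' reg <- generate_registry(city_template(), seed = 1)
#' sum(reg$pop_night)  # 10,500,000
#' sum(reg$pop_day)    # 11,600,000
generate_registry <- function(template = city_template(), seed = 1L,
                              concentration = 50) {
  stopifnot(inherits(template, "city_template"))
  if (template$base_population <= 0) {
    stop("`base_population` must be positive", call. = FALSE)
  }
  n_mun <- length(template$municipalities)
  rows <- with_seed(seed, {
    purrr::map_dfr(seq_len(n_mun), function(m) {
      mun <- template$municipalities[m]
      nbhds <- template$neighborhoods_per_district[[m]]
      purrr::map_dfr(seq_along(nbhds), function(d) {
        k <- nbhds[d]
        share <- stats::rgamma(k, shape = concentration)
        tibble::tibble(
          municipality = mun,
          district = sprintf("%s-D%02d", mun, d),
          weight_in_district = share / sum(share),
          n_in_district = k
        )
      })
    })
  })
  # hierarchical continuous target: municipality and district mass follow
  # neighborhood counts; within-district mass follows the Dirichlet draw
  total_n <- template$total_neighborhoods
  rows$target <- template$base_population *
    (rows$n_in_district / total_n) * rows$weight_in_district
  pop_night <- allocate_integer(template$base_population, rows$target)
  # guard against degenerate zero-person areas in tiny templates
  if (any(pop_night == 0) && template$base_population >= nrow(rows)) {
    deficit <- sum(pop_night == 0)
    donor <- which.max(pop_night)
    pop_night[pop_night == 0] <- 1
    pop_night[donor] <- pop_night[donor] - deficit
  }
  reg <- tibble::tibble(
    id = sprintf("NB%03d", seq_len(nrow(rows))),
    district = rows$district,
    municipality = rows$municipality,
    pop_night = pop_night
  )
  inflows <- template$commuter_net_inflow
  split_day_night_population(
    reg,
    tibble::tibble(municipality = names(inflows), net_inflow = unname(inflows))
  )
}

#' Generate a synthetic patient-level ED survey
#'
#' Emulates a hospital-arrival survey: each patient record carries the
#' neighborhood of origin (drawn proportionally to daytime population, since
#' attendance scales with the exposed population), a day/night period flag
#' (Bernoulli with day probability `true_day_share`), and an ambulance-use
#' flag (Bernoulli at that neighborhood's true rate).
#'
#' @param registry Neighborhood registry tibble with `id` and `pop_day`.
#' @param survey_n Number of patient records (default 1964).
#' @param true_ambulance_rate Either a single probability applied city-wide
#'   (default 0.093) or a named vector of per-neighborhood probabilities.
#' @param true_day_share Probability that a record is a daytime arrival
#'   (default 0.625).
#' @param seed Integer seed.
#' @return A tibble with columns `patient_id`, `neighborhood_id`, `period`
#'   (`"day"`/`"night"`), `used_ambulance` (0/1).
#' @export
#' @examples
#' reg <- generate_registry(city_template(), seed = 1)
#' svy <- generate_survey(reg, seed = 2)
#' mean(svy$used_ambulance)
generate_survey <- function(registry, survey_n = 1964,
                            true_ambulance_rate = 0.093,
                            true_day_share = 0.625, seed = 1L) {
  if (is.null(registry) || nrow(registry) == 0) {
    stop("`registry` must contain at least one neighborhood", call. = FALSE)
  }
  check_columns(registry, c("id", "pop_day"), "`registry`")
  stopifnot(survey_n >= 1,
            all(true_ambulance_rate >= 0 & true_ambulance_rate <= 1),
            true_day_share >= 0, true_day_share <= 1)
  rate <- if (length(true_ambulance_rate) == 1) {
    stats::setNames(rep(true_ambulance_rate, nrow(registry)), registry$id)
  } else {
    missing <- setdiff(registry$id, names(true_ambulance_rate))
    if (length(missing) > 0) {
      stop("`true_ambulance_rate` lacks entries for: ",
           paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
    }
    true_ambulance_rate[registry$id]
  }
  with_seed(seed, {
    nb <- sample(registry$id, size = survey_n, replace = TRUE,
                 prob = registry$pop_day)
    tibble::tibble(
      patient_id = seq_len(survey_n),
      neighborhood_id = nb,
      period = ifelse(stats::runif(survey_n) < true_day_share, "day", "night"),
      used_ambulance = as.integer(stats::runif(survey_n) < rate[nb])
    )
  })
}

#' Five-number summary of hospital ED volumes
#'
#' Minimum, first quartile, median, third quartile, maximum and sum, with
#' quartiles by linear interpolation between order statistics
#' ([stats::quantile()] type 7; the median of an even-sized sample is the
#' mean of the two central values).
#'
#' @param volumes Numeric vector of annual ED visit counts.
#' @return A named list with elements `min`, `q1`, `median`, `q3`, `max`, `sum`.
#' @export
#' @examples
#' five_number_summary(c(5, 1, 3, 2, 4))
five_number_summary <- function(volumes) {
  stopifnot(length(volumes) >= 1, all(is.finite(volumes)), all(volumes >= 0))
  q <- unname(stats::quantile(volumes, c(0.25, 0.5, 0.75), type = 7))
  list(min = min(volumes), q1 = q[1], median = q[2], q3 = q[3],
       max = max(volumes), sum = sum(volumes))
}

#' Construct a hospital volume sample
#'
#' Wraps raw annual ED volumes (or, when only published summary statistics
#' are available, the summary alone) into the container consumed by
#' [estimate_per_capita_scenarios()].
#'
#' @param volumes Numeric vector of annual ED visit counts, or `NULL` when
#'   only a summary is available.
#' @param summary Optional named list (`min`, `q1`, `median`, `q3`, `max`,
#'   `sum`); computed from `volumes` when omitted.
#' @return An object of class `hospital_volume_sample`.
#' @export
hospital_volume_sample <- function(volumes = NULL, summary = NULL) {
  if (is.null(volumes) && is.null(summary)) {
    stop("provide `volumes`, `summary`, or both", call. = FALSE)
  }
  if (is.null(summary)) {
    summary <- five_number_summary(volumes)
  }
  need <- c("min", "q1", "median", "q3", "max", "sum")
  if (!all(need %in% names(summary))) {
    stop("`summary` must contain: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(volumes)) {
    ref <- five_number_summary(volumes)
    if (!isTRUE(all.equal(ref[need], summary[need], tolerance = 1e-8))) {
      stop("`summary` is inconsistent with `volumes` under the type-7 quantile convention",
           call. = FALSE)
    }
  }
  structure(list(volumes = volumes, summary = summary[need]),
            class = "hospital_volume_sample")
}

#' @export
print.hospital_volume_sample <- function(x, ...) {
  cat("<hospital_volume_sample>",
      if (!is.null(x$volumes)) paste0("n = ", length(x$volumes)) else "(summary only)",
      "\n")
  s <- x$summary
  cat(sprintf("  min %s | Q1 %s | median %s | Q3 %s | max %s | sum %s\n",
              format(s$min, big.mark = ","), format(s$q1, big.mark = ","),
              format(s$median, big.mark = ","), format(s$q3, big.mark = ","),
              format(s$max, big.mark = ","), format(s$sum, big.mark = ",")))
  invisible(x)
}

#' Generate synthetic annual hospital ED volumes
#'
#' Draws right-skewed positive annual volumes from a log-normal law. The
#' defaults are centred on a median of about 24,600 visits with enough spread
#' that a 10-hospital draw typically brackets the low thousands to the high
#' tens of thousands.
#'
#' @param n_hospitals Number of hospitals sampled (default 10).
#' @param meanlog,sdlog Log-normal parameters.
#' @param seed Integer seed.
#' @return A `hospital_volume_sample` with integer volumes.
#' @export
#' @examples
#' generate_hospital_volumes(seed = 1)
generate_hospital_volumes <- function(n_hospitals = 10,
                                      meanlog = log(24629), sdlog = 0.95,
                                      seed = 1L) {
  stopifnot(n_hospitals >= 1, sdlog > 0)
  volumes <- with_seed(seed, {
    pmax(1, round(stats::rlnorm(n_hospitals, meanlog = meanlog, sdlog = sdlog)))
  })
  hospital_volume_sample(volumes)
}

#' Published ED volume summary for the Jakarta hospital sample
#'
#' The five-number summary of 2019 annual ED visits across the 10 surveyed
#' Jakarta hospitals (sum 266,931). The quartile values carry the half-unit
#' precision implied by the derived city totals (median 24,628.5, third
#' quartile 35,729.5); published tables round them to whole visits.
#'
#' @return A `hospital_volume_sample` holding the summary only.
#' @export
#' @examples
#' jakarta_ed_summary()$summary$median * 86
jakarta_ed_summary <- function() {
  hospital_volume_sample(summary = list(
    min = 1080, q1 = 12522, median = 24628.5, q3 = 35729.5,
    max = 66899, sum = 266931
  ))
}

#' Write a synthetic city to CSV files
#'
#' Generates and writes `neighborhoods.csv`, `survey.csv` and `hospitals.csv`
#' (plain UTF-8, comma-delimited, header row) so the estimation stages can be
#' run from files.
#'
#' @param out_dir Output directory (created if needed).
#' @param template A [city_template()].
#' @param seed Integer seed for all three generators.
#' @param survey_n,true_ambulance_rate,true_day_share Passed to
#'   [generate_survey()].
#' @param n_hospitals Passed to [generate_hospital_volumes()].
#' @return Invisibly, a named list of the three file paths.
#' @export
write_synthetic_city <- function(out_dir, template = city_template(),
                                 seed = 1L, survey_n = 1964,
                                 true_ambulance_rate = 0.093,
                                 true_day_share = 0.625, n_hospitals = 10) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  registry <- generate_registry(template, seed = seed)
  survey <- generate_survey(registry, survey_n = survey_n,
                            true_ambulance_rate = true_ambulance_rate,
                            true_day_share = true_day_share, seed = seed + 1L)
  hospitals <- generate_hospital_volumes(n_hospitals = n_hospitals,
                                         seed = seed + 2L)
  paths <- list(
    neighborhoods = file.path(out_dir, "neighborhoods.csv"),
    survey = file.path(out_dir, "survey.csv"),
    hospitals = file.path(out_dir, "hospitals.csv")
  )
  readr::write_csv(registry, paths$neighborhoods)
  readr::write_csv(survey, paths$survey)
  readr::write_csv(
    tibble::tibble(hospital_id = sprintf("H%02d", seq_along(hospitals$volumes)),
                   annual_ed_visits = hospitals$volumes),
    paths$hospitals
  )
  invisible(paths)
}
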