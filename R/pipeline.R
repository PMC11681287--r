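#' Pipeline configuration
#'
#' Bundles everything a full estimation run needs: either paths to the three
#' input CSVs (`neighborhoods.csv`, `survey.csv`, `hospitals.csv`) or, when
#' they are `NULL`, the synthetic-city template and generator settings used
#' to create them.
#'
#' @param seed Integer seed governing every random stage of the run.
#' @param out_dir Output directory for CSVs, the figure and the manifest.
#' @param neighborhoods_csv,survey_csv,hospitals_csv Optional paths to input
#'   CSVs; when `NULL` the corresponding table is generated synthetically.
#' @param template [city_template()] used when generating.
#' @param survey_n,true_ambulance_rate,true_day_share Generator settings for
#'   the synthetic survey.
#' @param n_hospitals_with_ed Number of ED-equipped hospitals the sample is
#'   scaled to (default 86).
#' @param population_baseline Resident population used as the per-capita
#'   denominator (default 10.5 million).
#' @param usage_rate Ambulance-usage rate for the emergency-care conversion;
#'   `NULL` (default) uses the pooled rate observed in the survey.
#' @param n_replicates Monte Carlo replicates (default 10,000).
#' @param use_rounded_rates Use two-decimal per-capita rates in the demand
#'   arithmetic (default `FALSE`).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, out_dir = tempfile("emsdemand-run-"),
                            neighborhoods_csv = NULL, survey_csv = NULL,
                            hospitals_csv = NULL,
                            template = city_template(),
                            survey_n = 1964, true_ambulance_rate = 0.093,
                            true_day_share = 0.625,
                            n_hospitals_with_ed = 86,
                            population_baseline = 10.5e6,
                            usage_rate = NULL, n_replicates = 10000,
                            use_rounded_rates = FALSE) {
  stopifnot(n_hospitals_with_ed >= 1, population_baseline > 0,
            n_replicates >= 2, survey_n >= 1)
  if (!is.null(usage_rate) && (usage_rate <= 0 || usage_rate > 1)) {
    stop("`usage_rate` must lie in (0, 1]", call. = FALSE)
  }
  for (p in c(neighborhoods_csv, survey_csv, hospitals_csv)) {
    if (!is.null(p) && !file.exists(p)) {
      stop("input file not found: ", p, call. = FALSE)
    }
  }
  structure(
    list(seed = as.integer(seed), out_dir = out_dir,
         neighborhoods_csv = neighborhoods_csv, survey_csv = survey_csv,
         hospitals_csv = hospitals_csv, template = template,
         survey_n = survey_n, true_ambulance_rate = true_ambulance_rate,
         true_day_share = true_day_share,
         n_hospitals_with_ed = n_hospitals_with_ed,
         population_baseline = population_baseline,
         usage_rate = usage_rate, n_replicates = n_replicates,
         use_rounded_rates = use_rounded_rates),
    class = "pipeline_config"
  )
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage %s] %s", stage, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full demand-estimation pipeline
#'
#' Sequences data acquisition (read CSVs or generate a synthetic city),
#' parameter estimation (day/night populations, period probabilities,
#' per-capita rate scenarios), ambulance-rate estimation (naive, weighted
#' naive, Monte Carlo with t-test comparisons), and scenario demand-table
#' assembly. All output CSVs plus a JSON manifest recording the seed,
#' package version and the nine scenario totals are written to
#' `config$out_dir`. Identical config and seed give byte-identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, the manifest as a list (class `ems_manifest`).
#' @export
#' @examples
#' \donttest{
#' cfg <- pipeline_config(seed = 1, n_replicates = 200)
#' manifest <- run_pipeline(cfg)
#' manifest$scenario_totals
#' }
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  dat <- run_stage("data", {
    if (is.null(config$neighborhoods_csv)) {
      registry <- generate_registry(config$template, seed = config$seed)
    } else {
      registry <- readr::read_csv(config$neighborhoods_csv,
                                  show_col_types = FALSE)
      check_columns(registry, c("id", "municipality", "pop_night", "pop_day"),
                    basename(config$neighborhoods_csv))
    }
    if (is.null(config$survey_csv)) {
      survey <- generate_survey(registry, survey_n = config$survey_n,
                                true_ambulance_rate = config$true_ambulance_rate,
                                true_day_share = config$true_day_share,
                                seed = config$seed + 1L)
    } else {
      survey <- readr::read_csv(config$survey_csv, show_col_types = FALSE)
      check_columns(survey, c("neighborhood_id", "used_ambulance"),
                    basename(config$survey_csv))
    }
    if (is.null(config$hospitals_csv)) {
      hospitals <- generate_hospital_volumes(seed = config$seed + 2L)
    } else {
      hv <- readr::read_csv(config$hospitals_csv, show_col_types = FALSE)
      check_columns(hv, "annual_ed_visits", basename(config$hospitals_csv))
      hospitals <- hospital_volume_sample(hv$annual_ed_visits)
    }
    readr::write_csv(registry, file.path(config$out_dir, "neighborhoods.csv"))
    readr::write_csv(survey, file.path(config$out_dir, "survey.csv"))
    readr::write_csv(
      tibble::tibble(hospital_id = sprintf("H%02d", seq_along(hospitals$volumes)),
                     annual_ed_visits = hospitals$volumes),
      file.path(config$out_dir, "hospitals.csv"))
    list(registry = registry, survey = survey, hospitals = hospitals)
  })

  params <- run_stage("parameters", {
    eps <- estimate_period_probabilities(dat$survey)
    scenarios <- estimate_per_capita_scenarios(
      dat$hospitals,
      n_hospitals_with_ed = config$n_hospitals_with_ed,
      population = config$population_baseline)
    list(eps = eps, scenarios = scenarios)
  })

  rates <- run_stage("rates", {
    counts <- aggregate_survey(dat$survey)
    estimates <- list(
      naive = naive_rate(counts),
      weighted_naive = weighted_naive_rate(counts, dat$registry),
      simulation = monte_carlo_rate(counts,
                                    n_replicates = config$n_replicates,
                                    seed = config$seed + 3L)
    )
    compare_or_na <- function(reference, label) {
      tryCatch(
        tidy(compare_to_reference(estimates$simulation, reference, label)),
        error = function(e) {
          warning("t-test vs ", label, " not available: ",
                  conditionMessage(e), call. = FALSE)
          tibble::tibble(reference_method = label, reference = reference,
                         t_statistic = NA_real_, df = NA_real_,
                         p_value = NA_real_)
        }
      )
    }
    comparisons <- dplyr::bind_rows(
      compare_or_na(estimates$naive$delta, "naive"),
      compare_or_na(estimates$weighted_naive$delta, "weighted_naive")
    )
    rates_tbl <- purrr::map_dfr(estimates, tidy)
    readr::write_csv(rates_tbl, file.path(config$out_dir, "rates.csv"))
    readr::write_csv(
      tibble::tibble(
        replicate = seq_along(estimates$simulation$replicate_means),
        mean_rate = estimates$simulation$replicate_means),
      file.path(config$out_dir, "replicates.csv"))
    list(counts = counts, estimates = estimates, table = rates_tbl,
         comparisons = comparisons, pooled = pooled_rate(counts))
  })

  demand <- run_stage("demand", {
    usage <- config$usage_rate %||% rates$pooled
    out <- build_scenario_table(dat$registry, params$eps, params$scenarios,
                                rates$estimates, usage_rate = usage,
                                use_rounded_rates = config$use_rounded_rates,
                                detail = TRUE)
    readr::write_csv(out$summary,
                     file.path(config$out_dir, "demand_summary.csv"))
    readr::write_csv(out$by_neighborhood,
                     file.path(config$out_dir, "demand_by_neighborhood.csv"))
    c(out, list(usage_rate = usage))
  })

  manifest <- structure(
    list(
      package = "emsdemand",
      version = as.character(utils::packageVersion("emsdemand")),
      seed = config$seed,
      out_dir = config$out_dir,
      settings = list(
        n_hospitals_with_ed = config$n_hospitals_with_ed,
        population_baseline = config$population_baseline,
        usage_rate = demand$usage_rate,
        n_replicates = config$n_replicates,
        use_rounded_rates = config$use_rounded_rates,
        survey_n = nrow(dat$survey)
      ),
      period_probabilities = list(eps_day = params$eps$eps_day,
                                  eps_night = params$eps$eps_night),
      scenarios = params$scenarios,
      pooled_usage_rate = rates$pooled,
      rates = rates$table,
      comparisons = rates$comparisons,
      scenario_totals = demand$summary,
      files = list(
        neighborhoods = "neighborhoods.csv", survey = "survey.csv",
        hospitals = "hospitals.csv", rates = "rates.csv",
        replicates = "replicates.csv", demand_summary = "demand_summary.csv",
        demand_by_neighborhood = "demand_by_neighborhood.csv"
      )
    ),
    class = "ems_manifest"
  )
  jsonlite::write_json(unclass(manifest),
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  invisible(manifest)
}

#' @export
print.ems_manifest <- function(x, ...) {
  cat("<ems_manifest>", x$package, x$version, "| seed", x$seed, "\n")
  cat("  pooled usage rate:", signif(x$pooled_usage_rate, 4), "\n")
  print(x$scenario_totals[, c("method", "rate_label", "lam", "delta",
                              "night_total", "day_total", "ambulance_total",
                              "emergency_care_total")])
  invisible(x)
}

read_manifest <- function(manifest) {
  if (inherits(manifest, "ems_manifest")) {
    return(manifest)
  }
  if (is.character(manifest) && length(manifest) == 1) {
    m <- jsonlite::read_json(manifest, simplifyVector = TRUE)
    m$out_dir <- m$out_dir %||% dirname(manifest)
    m$scenario_totals <- tibble::as_tibble(m$scenario_totals)
    return(structure(m, class = "ems_manifest"))
  }
  stop("`manifest` must be an ems_manifest or a path to manifest.json",
       call. = FALSE)
}

#' Render a human-readable run report
#'
#' Writes `report.md` in the run's output directory: a markdown table of the
#' nine scenario totals plus, when simulation replicates are available, a
#' density figure of the replicate means with vertical markers at the naive
#' and weighted-naive estimates. Degenerate replicates (all equal) produce a
#' warning and a table-only report rather than a broken figure.
#'
#' @param manifest An `ems_manifest` from [run_pipeline()], or a path to a
#'   `manifest.json`.
#' @return Invisibly, the path to the report file.
#' @export
render_report <- function(manifest) {
  m <- read_manifest(manifest)
  out_dir <- m$out_dir
  lines <- c(
    "# Annual ambulance and emergency-care demand estimates",
    "",
    sprintf("Seed %d; %s replicates; pooled ambulance usage %.4f.",
            m$seed, format(m$settings$n_replicates, big.mark = ","),
            m$pooled_usage_rate),
    "",
    "| Model | Rate per capita ED visits | Rate ambulance use | Nighttime est. | Daytime est. | Total ambulance needs | Total annual emergency care need |",
    "|---|---|---|---|---|---|---|"
  )
  st <- m$scenario_totals
  lines <- c(lines, sprintf(
    "| %s | %.2f | %.5f | %s | %s | %s | %s |",
    st$method, st$lam, st$delta,
    format(st$night_total, big.mark = ","),
    format(st$day_total, big.mark = ","),
    format(st$ambulance_total, big.mark = ","),
    format(st$emergency_care_total, big.mark = ",")))

  replicates_path <- file.path(out_dir, m$files$replicates %||% "replicates.csv")
  fig_done <- FALSE
  if (file.exists(replicates_path)) {
    reps <- readr::read_csv(replicates_path, show_col_types = FALSE)
    if (stats::sd(reps$mean_rate) == 0) {
      warning("replicate means are degenerate; skipping the density figure",
              call. = FALSE)
    } else {
      refs <- st[!duplicated(st$method), c("method", "delta")]
      refs <- refs[refs$method != "simulation", ]
      p <- plot_replicate_means(reps$mean_rate,
                                references = setNames(refs$delta, refs$method))
      fig_path <- file.path(out_dir, "replicate_means.png")
      ggplot2::ggsave(fig_path, p, width = 7, height = 4.5, dpi = 150)
      lines <- c(lines, "",
                 "![Distribution of simulation replicate means](replicate_means.png)")
      fig_done <- TRUE
    }
  }
  if (!fig_done) {
    lines <- c(lines, "", "_No simulation replicates available; table-only report._")
  }
  path <- file.path(out_dir, "report.md")
  writeLines(lines, path)
  invisible(path)
}
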