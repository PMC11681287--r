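#' Aggregate a patient-level survey to neighborhood counts
#'
#' Collapses patient records to one row per neighborhood appearing in the
#' survey: the number surveyed and the number who used an ambulance. Totals
#' are conserved (column sums equal the survey size and the ambulance-user
#' count).
#'
#' @param survey Tibble with `neighborhood_id` and `used_ambulance` (0/1).
#' @return A tibble with columns `neighborhood_id`, `n_total`, `n_ambulance`.
#' @export
#' @examples
#' svy <- tibble::tibble(neighborhood_id = c("a", "a", "b"),
#'                       used_ambulance = c(1, 0, 0))
#' aggregate_survey(svy)
aggregate_survey <- function(survey) {
  if (is.null(survey) || nrow(survey) == 0) {
    return(tibble::tibble(neighborhood_id = character(),
                          n_total = integer(), n_ambulance = integer()))
  }
  check_columns(survey, c("neighborhood_id", "used_ambulance"), "`survey`")
  survey |>
    dplyr::group_by(neighborhood_id = .data$neighborhood_id) |>
    dplyr::summarise(n_total = dplyr::n(),
                     n_ambulance = sum(.data$used_ambulance),
                     .groups = "drop")
}

#' Pooled ambulance-usage rate
#'
#' Total ambulance users over total surveyed patients, the city-level usage
#' rate used to convert ambulance needs into total emergency-care need.
#'
#' @param counts Neighborhood counts from [aggregate_survey()].
#' @return A single probability.
#' @export
#' @examples
#' pooled_rate(tibble::tibble(neighborhood_id = "x",
#'                            n_total = 1964, n_ambulance = 183))
pooled_rate <- function(counts) {
  check_columns(counts, c("n_total", "n_ambulance"), "`counts`")
  total <- sum(counts$n_total)
  if (total < 1) {
    stop("cannot estimate a pooled rate from zero surveyed patients",
         call. = FALSE)
  }
  sum(counts$n_ambulance) / total
}

new_rate_estimate <- function(method, delta, n_neighborhoods,
                              ci_low = NA_real_, ci_high = NA_real_,
                              replicate_means = NULL,
                              n_replicates = NA_integer_, seed = NA_integer_) {
  structure(
    list(method = method, delta = delta, n_neighborhoods = n_neighborhoods,
         ci_low = ci_low, ci_high = ci_high,
         replicate_means = replicate_means,
         n_replicates = n_replicates, seed = seed),
    class = "ambulance_rate_estimate"
  )
}

#' @export
print.ambulance_rate_estimate <- function(x, ...) {
  cat(sprintf("<ambulance_rate_estimate> method: %s | delta = %.5f", x$method,
              x$delta))
  if (!is.na(x$ci_low)) {
    cat(sprintf(" (95%% CI %.5f-%.5f, %d replicates)", x$ci_low, x$ci_high,
                x$n_replicates))
  }
  cat(sprintf(" | %d neighborhoods\n", x$n_neighborhoods))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.ambulance_rate_estimate <- function(x, ...) {
  tibble::tibble(method = x$method, delta = x$delta,
                 ci_low = x$ci_low, ci_high = x$ci_high,
                 n_neighborhoods = x$n_neighborhoods,
                 n_replicates = x$n_replicates, seed = x$seed)
}

#' @exportS3Method generics::glance
glance.ambulance_rate_estimate <- function(x, ...) {
  tidy.ambulance_rate_estimate(x)
}

eligible_counts <- function(counts) {
  check_columns(counts, c("neighborhood_id", "n_total", "n_ambulance"),
                "`counts`")
  if (any(counts$n_ambulance > counts$n_total) || any(counts$n_ambulance < 0)) {
    stop("invalid counts: need 0 <= n_ambulance <= n_total", call. = FALSE)
  }
  out <- dplyr::filter(counts, .data$n_total >= 1)
  if (nrow(out) == 0) {
    stop("no neighborhood has any surveyed patients", call. = FALSE)
  }
  out
}

#' Naive (unweighted-mean) ambulance-use rate
#'
#' The naive estimator treats the city-wide ambulance-use rate as the
#' unweighted mean of the per-neighborhood observed proportions; every
#' surveyed neighborhood counts equally regardless of its population or
#' sample size. Neighborhoods with no surveyed patients are excluded.
#'
#' @param counts Neighborhood counts from [aggregate_survey()].
#' @return An `ambulance_rate_estimate` with `method = "naive"`.
#' @export
naive_rate <- function(counts) {
  ok <- eligible_counts(counts)
  new_rate_estimate("naive", mean(ok$n_ambulance / ok$n_total), nrow(ok))
}

#' Population-weighted naive ambulance-use rate
#'
#' Like [naive_rate()], but each neighborhood's observed proportion is
#' weighted by its share of the daytime population, so populous areas carry
#' more of the city-wide rate.
#'
#' @param counts Neighborhood counts from [aggregate_survey()].
#' @param registry Registry tibble with `id` and `pop_day` covering every
#'   counted neighborhood.
#' @return An `ambulance_rate_estimate` with `method = "weighted_naive"`.
#' @export
weighted_naive_rate <- function(counts, registry) {
  ok <- eligible_counts(counts)
  check_columns(registry, c("id", "pop_day"), "`registry`")
  joined <- dplyr::left_join(ok, registry[, c("id", "pop_day")],
                             by = c(neighborhood_id = "id"))
  if (any(is.na(joined$pop_day))) {
    stop("registry lacks populations for surveyed neighborhood(s): ",
         paste(utils::head(joined$neighborhood_id[is.na(joined$pop_day)], 5),
               collapse = ", "), call. = FALSE)
  }
  w <- joined$pop_day / sum(joined$pop_day)
  new_rate_estimate("weighted_naive",
                    sum(w * joined$n_ambulance / joined$n_total), nrow(joined))
}

#' Monte Carlo (parametric binomial bootstrap) ambulance-use rate
#'
#' Propagates sampling variability in the sparse per-neighborhood counts: in
#' each replicate, every surveyed neighborhood's ambulance count is redrawn
#' from Binomial(n_total, observed proportion), and the replicate statistic
#' is the unweighted mean of the resampled proportions. The estimate is the
#' mean of replicate means; by the central limit theorem the replicate means
#' are approximately normal, so the 95% confidence interval is
#' `delta +/- 1.96 * sd(replicate_means) / sqrt(n_replicates)`.
#'
#' @param counts Neighborhood counts from [aggregate_survey()].
#' @param n_replicates Number of bootstrap replicates (default 10,000).
#' @param seed Integer seed; identical seeds give identical replicate means.
#' @param conf_multiplier Normal critical value for the CI (default 1.96).
#' @return An `ambulance_rate_estimate` with `method = "simulation"`,
#'   carrying `replicate_means`, the CI, and seed metadata.
#' @export
monte_carlo_rate <- function(counts, n_replicates = 10000, seed = 1L,
                             conf_multiplier = 1.96) {
  if (n_replicates < 2) {
    stop("`n_replicates` must be at least 2", call. = FALSE)
  }
  ok <- eligible_counts(counts)
  n <- ok$n_total
  p <- ok$n_ambulance / ok$n_total
  k <- nrow(ok)
  replicate_means <- with_seed(seed, {
    draws <- matrix(stats::rbinom(k * n_replicates, size = n, prob = p) / n,
                    nrow = k)
    colMeans(draws)
  })
  delta <- mean(replicate_means)
  se <- stats::sd(replicate_means) / sqrt(n_replicates)
  new_rate_estimate("simulation", delta, k,
                    ci_low = delta - conf_multiplier * se,
                    ci_high = delta + conf_multiplier * se,
                    replicate_means = replicate_means,
                    n_replicates = as.integer(n_replicates),
                    seed = as.integer(seed))
}

#' Compare simulation replicate means to a reference rate
#'
#' One-sample, two-sided t-test of the Monte Carlo replicate means against a
#' scalar reference (a naive or weighted-naive estimate), testing whether the
#' simulation distribution is centred on the reference value.
#'
#' @param estimate An `ambulance_rate_estimate` from [monte_carlo_rate()].
#' @param reference Scalar reference rate.
#' @param reference_method Label recorded for the reference (default
#'   `"reference"`).
#' @return An object of class `rate_comparison` with `t_statistic`, `df`,
#'   `p_value`, `reference`, `reference_method`.
#' @export
compare_to_reference <- function(estimate, reference,
                                 reference_method = "reference") {
  stopifnot(inherits(estimate, "ambulance_rate_estimate"))
  rm_ <- estimate$replicate_means
  if (is.null(rm_) || length(rm_) < 2) {
    stop("`estimate` must carry replicate means (use monte_carlo_rate())",
         call. = FALSE)
  }
  if (stats::sd(rm_) == 0) {
    stop("replicate means are degenerate (zero variance); t-test undefined",
         call. = FALSE)
  }
  tt <- stats::t.test(rm_, mu = reference, alternative = "two.sided")
  structure(
    list(reference_method = reference_method, reference = reference,
         t_statistic = unname(tt$statistic), df = unname(tt$parameter),
         p_value = tt$p.value),
    class = "rate_comparison"
  )
}

#' @export
print.rate_comparison <- function(x, ...) {
  cat(sprintf(
    "<rate_comparison> vs %s (%.5f): t = %.2f, df = %d, p %s\n",
    x$reference_method, x$reference, x$t_statistic, x$df,
    if (x$p_value < 0.001) "< 0.001" else sprintf("= %.3f", x$p_value)))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.rate_comparison <- function(x, ...) {
  tibble::tibble(reference_method = x$reference_method,
                 reference = x$reference,
                 t_statistic = x$t_statistic, df = x$df, p_value = x$p_value)
}
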