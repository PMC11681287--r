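# Shared fixture builders; everything is generated in code at test time.

# a minimal registry: k neighborhoods in one municipality
tiny_registry <- function(k = 4, pop_night = NULL, municipality = "M") {
  pop_night <- pop_night %||% rep(1000, k)
  tibble::tibble(
    id = sprintf("a%02d", seq_len(k)),
    district = paste0(municipality, "-D01"),
    municipality = municipality,
    pop_night = pop_night,
    pop_day = pop_night
  )
}

# random per-neighborhood survey counts at a true rate
make_counts <- function(k, n_range = c(5, 40), rate = 0.093, seed = 1) {
  withr::with_seed(seed, {
    n <- sample(seq(n_range[1], n_range[2]), k, replace = TRUE)
    tibble::tibble(
      neighborhood_id = sprintf("a%02d", seq_len(k)),
      n_total = n,
      n_ambulance = stats::rbinom(k, n, rate)
    )
  })
}

# a simulation-shaped estimate with chosen replicate means, for t-test cases
fake_simulation_estimate <- function(replicate_means, seed = 0L) {
  delta <- mean(replicate_means)
  se <- stats::sd(replicate_means) / sqrt(length(replicate_means))
  structure(
    list(method = "simulation", delta = delta,
         n_neighborhoods = NA_integer_,
         ci_low = delta - 1.96 * se, ci_high = delta + 1.96 * se,
         replicate_means = replicate_means,
         n_replicates = length(replicate_means), seed = seed),
    class = "ambulance_rate_estimate"
  )
}

# independent five-number-summary oracle: sort and interpolate by hand,
# never calling stats::quantile()
fivenum_oracle <- function(x) {
  s <- sort(x)
  n <- length(s)
  interp <- function(p) {
    h <- (n - 1) * p + 1
    lo <- floor(h)
    hi <- ceiling(h)
    s[lo] + (h - lo) * (s[hi] - s[lo])
  }
  list(min = s[1], q1 = interp(0.25), median = interp(0.5),
       q3 = interp(0.75), max = s[n], sum = sum(s))
}

`%||%` <- rlang::`%||%`
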