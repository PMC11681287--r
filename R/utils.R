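#' Round half away from zero
#'
#' Reporting convention for aggregate demand figures: ties round away from
#' zero (so 0.5 -> 1), unlike [base::round()]'s round-half-to-even.
#'
#' @param x Numeric vector.
#' @return Numeric vector of rounded values.
#' @export
#' @examples
#' round_half_up(c(0.5, 1.5, 2.49))
round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

#' Allocate an integer total proportionally with largest-remainder correction
#'
#' Splits `total` across bins proportionally to `weights`, returning integers
#' that sum exactly to `round(total)`. Fractional remainders are resolved by
#' awarding the leftover units to the bins with the largest remainders
#' (largest-remainder / Hamilton apportionment). Negative totals are allocated
#' by apportioning the magnitude and negating.
#'
#' @param total Scalar total to allocate (rounded to an integer first).
#' @param weights Positive numeric weights, one per bin.
#' @return Integer-valued numeric vector summing to `round(total)`.
#' @export
#' @examples
#' allocate_integer(100, c(1, 1))
#' allocate_integer(-100, c(300, 100))
allocate_integer <- function(total, weights) {
  stopifnot(length(total) == 1, is.finite(total), length(weights) >= 1)
  if (any(!is.finite(weights)) || any(weights < 0) || sum(weights) <= 0) {
    stop("`weights` must be nonnegative with a positive sum", call. = FALSE)
  }
  total <- round(total)
  if (total < 0) {
    return(-allocate_integer(-total, weights))
  }
  target <- total * weights / sum(weights)
  base <- floor(target)
  leftover <- total - sum(base)
  if (leftover > 0) {
    frac <- target - base
    top <- order(frac, weights, decreasing = TRUE)[seq_len(leftover)]
    base[top] <- base[top] + 1
  }
  base
}

# Evaluate code under a temporary RNG state; the caller's stream is untouched.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Shared column checks with a readable error naming the offender.
check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop(what, " is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(df)
}
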