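`%||%` <- function(x, y) if (is.null(x)) y else x

#' Convert a weekly amount to a monthly amount
#'
#' Fixed convention used throughout the package: pounds/week * 52 / 12.
#'
#' @param x Amount in pounds per week.
#' @return Amount in pounds per month.
#' @export
weekly_to_monthly <- function(x) x * 52 / 12

#' Weighted median
#'
#' @param x Numeric vector.
#' @param w Positive weights, same length as `x`.
#' @return The smallest `x` at which the cumulative weight reaches half the
#'   total weight (lower weighted median).
#' @export
weighted_median <- function(x, w) {
  stopifnot(length(x) == length(w), all(w > 0))
  o <- order(x)
  x <- x[o]
  w <- w[o]
  cw <- cumsum(w)
  x[which(cw >= sum(w) / 2)[1]]
}

#' Weighted Gini coefficient
#'
#' Gini coefficient of a weighted distribution, computed from the weighted
#' Lorenz curve. Equivalent to half the weighted mean absolute difference
#' divided by the weighted mean.
#'
#' @param x Non-negative incomes.
#' @param w Positive weights.
#' @return Gini coefficient in `[0, 1)`.
#' @export
weighted_gini <- function(x, w = rep(1, length(x))) {
  stopifnot(length(x) == length(w))
  if (any(w <= 0)) stop("weights must be positive")
  o <- order(x)
  x <- x[o]
  w <- w[o]
  p <- w / sum(w)
  mu <- sum(p * x)
  if (mu == 0) return(0)
  # Gini = (1/mu) * sum_i p_i x_i (F_i + F_{i-1}) - 1 with F the cum. weight
  f <- cumsum(p)
  sum(p * x * (2 * f - p)) / mu - 1
}

# Seeded evaluation that restores the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# Derive a stage-specific 31-bit sub-seed from a master seed.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647L)
}

assert_proportions <- function(p, what) {
  if (is.null(names(p)) || any(!nzchar(names(p)))) {
    stop(what, " proportions must be a named vector", call. = FALSE)
  }
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
    stop(what, " proportions must be non-negative and sum to 1", call. = FALSE)
  }
  invisible(p)
}

sample_categorical <- function(n, probs) {
  names(probs)[sample.int(length(probs), n, replace = TRUE, prob = probs)]
}
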