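#' Round half away from zero
#'
#' Integer rounding used when decoding optimizer positions to count-valued
#' hyperparameters: 0.5 always rounds away from zero (250.6 -> 251, -2.5 -> -3),
#' unlike base [round()]'s round-half-even.
#'
#' @param x Numeric vector.
#' @return Numeric vector of rounded values.
#' @export
round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

#' Largest-remainder integer allocation
#'
#' Splits `n` items into groups proportional to `fractions` so the group sizes
#' are integers summing exactly to `n`: floor the quotas, then hand the leftover
#' seats to the largest fractional remainders. 774 at (0.64, 0.16, 0.20) gives
#' exactly (495, 124, 155).
#'
#' @param n Non-negative integer total.
#' @param fractions Numeric vector of non-negative fractions summing to 1
#'   (tolerance 1e-9).
#' @return Integer vector, same length as `fractions`, summing to `n`.
#' @export
#' @examples
#' largest_remainder(774, c(0.64, 0.16, 0.20))
largest_remainder <- function(n, fractions) {
  if (length(n) != 1L || is.na(n) || n < 0) {
    stop("`n` must be a single non-negative integer.", call. = FALSE)
  }
  if (any(fractions < 0) || abs(sum(fractions) - 1) > 1e-9) {
    stop("`fractions` must be non-negative and sum to 1 (tolerance 1e-9).",
         call. = FALSE)
  }
  quota <- n * fractions
  sizes <- floor(quota)
  short <- as.integer(round(n - sum(sizes)))
  if (short > 0L) {
    top <- order(quota - sizes, decreasing = TRUE)[seq_len(short)]
    sizes[top] <- sizes[top] + 1
  }
  as.integer(sizes)
}

# Binary columns are encoded 0/1 throughout the package.
is_binary_col <- function(x) {
  u <- unique(x[!is.na(x)])
  length(u) <= 2 && all(u %in% c(0, 1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
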