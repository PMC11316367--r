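#' Round half away from zero
#'
#' Presentation rounding used for headline percentages.  Unlike [round()]
#' (banker's rounding), exact halves move away from zero, which is how
#' administrative reports round: `round_half_up(0.5) == 1`,
#' `round_half_up(-0.5) == -1`.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 0).
#' @return Numeric vector of the same length as `x`.
#' @export
#' @examples
#' round_half_up(c(2.5, -2.5, 4.513))  # 3 -3 5
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Largest-remainder apportionment: integer vector summing exactly to `total`,
# proportional to non-negative weights. Ties broken by first occurrence.
largest_remainder <- function(weights, total) {
  stopifnot(total >= 0, all(weights >= 0))
  if (length(weights) == 0L) return(integer(0))
  if (sum(weights) == 0) {
    out <- integer(length(weights))
    if (total > 0) out[1L] <- as.integer(total)
    return(out)
  }
  quota <- weights / sum(weights) * total
  base <- floor(quota)
  short <- as.integer(round(total - sum(base)))
  if (short > 0) {
    idx <- order(quota - base, decreasing = TRUE)[seq_len(short)]
    base[idx] <- base[idx] + 1
  }
  as.integer(base)
}

# Format a double so read.csv() recovers it bit-exactly.
format_full <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) return("")
    if (!is.na(v) && v == trunc(v) && abs(v) < 1e15) {
      return(sprintf("%.0f", v))
    }
    sprintf("%.17g", v)
  }, character(1))
  out
}
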