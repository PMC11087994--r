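#' Round half away from zero
#'
#' Commercial rounding used for all reported percentages and patient counts:
#' ties go away from zero (`round_half_up(0.5) == 1`), unlike base R's
#' round-half-to-even. Reported accessibility shares such as 45.0% or 69.7%
#' only reproduce under this rule.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places to keep.
#' @return Numeric vector rounded to `digits` decimals.
#' @export
#' @examples
#' round_half_up(896.604)        # 897
#' round_half_up(45.0238, 1)     # 45.0
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# percent of total, 1 decimal, NA-safe for empty denominators
pct1 <- function(covered, total) {
  out <- round_half_up(100 * covered / total, 1)
  out[!is.finite(out)] <- NA_real_
  out
}

# integer allocation preserving the exact total (largest remainder method)
largest_remainder <- function(weights, total) {
  stopifnot(total >= 0, all(weights >= 0))
  if (sum(weights) == 0) weights <- rep(1, length(weights))
  quota <- total * weights / sum(weights)
  base <- floor(quota)
  left <- total - sum(base)
  if (left > 0) {
    take <- order(quota - base, decreasing = TRUE)[seq_len(left)]
    base[take] <- base[take] + 1
  }
  as.integer(base)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_config <- function(msg) stop(msg, call. = FALSE)
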