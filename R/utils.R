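#' Round half away from zero
#'
#' Commercial ("half-up") rounding to a fixed number of decimal places, the
#' convention used for every reported per-100,000 figure, percentage and
#' person count in this package. Base R's `round()` rounds half to even,
#' which would turn e.g. 9.65 into 9.6 rather than the reported 9.7.
#'
#' @param x Numeric vector (nonnegative in all package uses).
#' @param digits Number of decimal places to keep.
#' @return Numeric vector rounded half-up to `digits` decimals.
#' @examples
#' round_half_up(1.25, 1) # 1.3
#' round_half_up(c(20.78, 69.62, 9.595) , 1)
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  # the tiny offset compensates binary representation of decimal inputs
  # (e.g. 9.595 * 10 stored just below 95.95)
  floor(x * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

#' Largest-remainder integer apportionment
#'
#' Scales a vector of counts and rounds to integers so that the rounded
#' values sum to the half-up-rounded scaled total. Used to derive reduced-
#' scale generator configurations whose composition matches a reference
#' composition as closely as integer counts allow.
#'
#' @param counts Nonnegative numeric vector of reference counts.
#' @param scale Positive scaling factor.
#' @return Integer vector, same length and names as `counts`, summing to
#'   `round_half_up(sum(counts) * scale)`.
#' @export
largest_remainder <- function(counts, scale = 1) {
  stopifnot(is.numeric(counts), all(counts >= 0), scale > 0)
  target <- counts * scale
  total <- round_half_up(sum(target))
  base <- floor(target + sqrt(.Machine$double.eps))
  short <- total - sum(base)
  if (short > 0) {
    rem <- target - base
    # ties broken by position for determinism
    top <- order(rem, decreasing = TRUE)[seq_len(short)]
    base[top] <- base[top] + 1
  }
  as.integer(setNames(base, names(counts)))
}

# split a space-separated token string into a character vector ("" -> none)
split_tokens <- function(x) {
  out <- strsplit(x, " ", fixed = TRUE)
  lapply(out, function(v) v[nzchar(v)])
}

# join tokens canonically (sorted, space-separated)
join_tokens <- function(...) {
  v <- sort(unique(c(...)))
  paste(v[nzchar(v)], collapse = " ")
}

# deterministic decimal formatting for XML serialisation: a pure function of
# the double, so format(as.numeric(format(x))) == format(x)
format_number <- function(x) {
  format(x, digits = 15, scientific = FALSE, trim = TRUE)
}

assert_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
}
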