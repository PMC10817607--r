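#' @useDynLib centroscan, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang %||% abort warn inform
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr arrange bind_rows filter group_by left_join mutate n
#'   rename select summarise ungroup distinct slice pull across
#' @importFrom stats median mad rnorm rpois rbinom runif setNames
#' @importFrom utils head tail
NULL

#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; reported percentages and table
#' values in this package are defined with conventional half-up rounding.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

cs_stop <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
cs_warn <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == floor(x)

# run length of consecutive TRUEs starting at each position (step 1)
run_start_lengths <- function(o) {
  if (length(o) == 0L) return(integer(0))
  rev(run_end_lengths(rev(o)))
}

# run length of consecutive TRUEs ending at each position
run_end_lengths <- function(o) {
  n <- length(o)
  if (n == 0L) return(integer(0))
  i <- seq_len(n)
  last_false <- cummax(ifelse(o, 0L, i))
  as.integer(ifelse(o, i - last_false, 0L))
}

# centered moving mean with shrinking window at the edges
moving_mean <- function(x, width = 3L) {
  n <- length(x)
  if (n == 0L || width <= 1L) return(x)
  half <- (width - 1L) %/% 2L
  cs <- c(0, cumsum(x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}
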