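#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm runif median sd predict
#' @importFrom utils read.csv write.csv head
#' @importFrom grDevices contourLines
NULL

# stop() wrapper carrying a condition class so callers/tests can
# distinguish validation errors from unexpected failures
ck_stop <- function(msg, class = "chalkcam_error", call. = FALSE) {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = NULL)))
}

assert_that <- function(ok, msg, class = "chalkcam_validation_error") {
  if (!isTRUE(ok)) ck_stop(msg, class = class)
  invisible(TRUE)
}

is_count <- function(x) length(x) == 1 && is.numeric(x) && !is.na(x) &&
  x == as.integer(x) && x >= 0

is_number <- function(x) length(x) == 1 && is.numeric(x) && !is.na(x)

#' Round half-up to a fixed number of decimals
#'
#' Reported percentages use conventional half-up rounding (so 83.125 prints
#' as 83.13), unlike base [round()] which rounds half to even.
#'
#' @param x numeric vector, assumed non-negative for the half-up convention.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

# run code with a fixed RNG seed without disturbing the caller's RNG state;
# seed = NULL leaves the RNG alone
with_seed_ <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(as.integer(seed), code)
}

# derive reproducible sub-seeds (< 2^31) from one master seed
derive_seeds <- function(seed, n) {
  with_seed_(seed, sample.int(.Machine$integer.max, n))
}

# clip numeric array to [lo, hi]
clip01 <- function(x, lo = 0, hi = 255) pmin(pmax(x, lo), hi)
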