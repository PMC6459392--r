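#' Round half away from zero
#'
#' Commercial ("half-up") rounding, as used in printed screening-programme
#' tables. Base [round()] rounds half to even, which disagrees with printed
#' values such as 41.685 -> 41.7.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 0).
#' @return numeric vector rounded half-up at `digits` decimals.
#' @examples
#' round_half_up(41.685, 1) # 41.7
#' round_half_up(5068.8)    # 5069
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# stop() with a condition class so callers/tests can distinguish
# domain errors (bad values), validation errors and not-found errors.
mf_stop <- function(msg, class) {
  stop(structure(
    class = c(class, "mammofleet_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

stop_domain     <- function(msg) mf_stop(msg, "mammofleet_domain_error")
stop_not_found  <- function(msg) mf_stop(msg, "mammofleet_not_found_error")
stop_validation <- function(msg) mf_stop(msg, "mammofleet_validation_error")

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0) {
    stop_domain(sprintf("`%s` must be a single positive number, got %s",
                        name, deparse(x)))
  }
  invisible(x)
}

check_nonnegative <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0) {
    stop_domain(sprintf("`%s` must be a single nonnegative number, got %s",
                        name, deparse(x)))
  }
  invisible(x)
}
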