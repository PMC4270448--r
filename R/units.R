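#' Time and rate units
#'
#' Rates in this package always carry an explicit reciprocal-time unit tag
#' (`"per_s"` or `"per_min"`), and time courses carry the matching time unit
#' (`"s"` or `"min"`). Units are never inferred from magnitudes: cruciform
#' cleavage experiments are conventionally reported in min^-1 while
#' single-turnover strand cleavage is reported in s^-1, and silent inference
#' across that split would be dangerous. `convert_rate()` is the explicit
#' converter.
#'
#' @param x numeric vector of rate constants.
#' @param from,to unit tags, one of `"per_s"`, `"per_min"`.
#' @return `convert_rate()`: the rates expressed in the `to` unit.
#' @examples
#' convert_rate(0.008, "per_s", "per_min")  # 0.48 min^-1
#' @export
convert_rate <- function(x, from = c("per_s", "per_min"),
                         to = c("per_s", "per_min")) {
  from <- match.arg(from)
  to <- match.arg(to)
  if (!is.numeric(x)) stop_domain("'x' must be numeric")
  # per_s -> per_min multiplies by 60 (more events per minute)
  factor <- c(per_s = 1, per_min = 60)
  x * factor[[to]] / factor[[from]]
}

time_units <- c("s", "min")
rate_units <- c("per_s", "per_min")

rate_unit_for <- function(time_unit) paste0("per_", time_unit)
time_unit_for <- function(rate_unit) sub("^per_", "", rate_unit)

check_time_unit <- function(unit) {
  if (!is.character(unit) || length(unit) != 1L || !unit %in% time_units) {
    stop_domain(sprintf("time unit must be one of %s",
                        paste(sQuote(time_units), collapse = ", ")))
  }
  unit
}

check_rate_unit <- function(unit) {
  if (!is.character(unit) || length(unit) != 1L || !unit %in% rate_units) {
    stop_domain(sprintf("rate unit must be one of %s",
                        paste(sQuote(rate_units), collapse = ", ")))
  }
  unit
}
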