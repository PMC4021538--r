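#' Time-unit conversions
#'
#' The model's canonical internal time unit is the continuous 3-month cycle.
#' Disease-progression rates are expressed per cycle, while window widths and
#' the symptom-onset error standard deviation are conventionally quoted in
#' weeks, and life expectancies in months or years. One cycle is 13 weeks or
#' 3 months; one year is 4 cycles.
#'
#' @param x numeric vector of durations.
#' @return numeric vector of durations in cycles.
#' @name units
NULL

#' @rdname units
#' @export
weeks_to_cycles <- function(x) x / 13

#' @rdname units
#' @export
months_to_cycles <- function(x) x / 3

#' @rdname units
#' @export
years_to_cycles <- function(x) x * 4

#' @rdname units
#' @export
cycles_to_weeks <- function(x) x * 13
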