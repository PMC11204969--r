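`%||%` <- function(a, b) if (is.null(a)) b else a

DAYS_PER_YEAR <- 365.25

#' @keywords internal
stop_field <- function(field, msg) {
  stop(sprintf("invalid '%s': %s", field, msg), call. = FALSE)
}

check_prob <- function(x, field) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0) || any(x > 1))
    stop_field(field, "must be a proportion in [0, 1]")
  invisible(x)
}

check_pos <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0)
    stop_field(field, "must be a single positive number")
  invisible(x)
}

# Derive a reproducible stage seed from a base seed; keeps the result a
# valid 32-bit integer whatever small integer the caller passes.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset * 104729) %% 2147483647L)
}

years_between <- function(from, to) {
  as.numeric(difftime(to, from, units = "days")) / DAYS_PER_YEAR
}

#' Format a count with its percentage
#'
#' Renders a cell of a demographics table as `"count (pct%)"` with the
#' percentage rounded to one decimal place, e.g. `fmt_count_pct(112, 301)`
#' gives `"112 (37.2%)"`.
#'
#' @param count integer numerator.
#' @param total integer denominator (> 0).
#' @return character scalar.
#' @export
fmt_count_pct <- function(count, total) {
  stopifnot(total > 0)
  sprintf("%d (%.1f%%)", count, round(100 * count / total, 1))
}
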