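#' Round half away from zero
#'
#' Commercial ("half-up") rounding. `round()` in R rounds half to even,
#' which does not reproduce per-participant money values derived from
#' printed cost tables (e.g. 12.375 must become 12.38). Amounts are kept
#' at full precision throughout the pipeline; this rounding is applied
#' only at presentation or when a per-participant table is materialised.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 2, i.e. cents).
#' @return `x` rounded half away from zero to `digits` places.
#' @examples
#' round_half_up(12.375) # 12.38; round() would give 12.38 or 12.37
#' round_half_up(1.005)
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  # kill binary representation error (1.005 * 100 == 100.49999...)
  # before applying the half-up rule
  sign(x) * floor(round(abs(x) * p, 9) + 0.5) / p
}

# stop with a classed validation error listing offending rows
validation_error <- function(msg, rows = NULL, values = NULL) {
  details <- NULL
  if (!is.null(rows)) {
    details <- paste0(
      "row ", rows,
      if (!is.null(values)) paste0(": ", values) else ""
    )
  }
  abort(c(msg, details), class = "boostercost_validation_error")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# match.arg with a clearer error for user-facing enum args
check_enum <- function(value, allowed, what) {
  if (length(value) != 1 || is.na(value) || !value %in% allowed) {
    abort(
      sprintf(
        "`%s` must be one of %s, not %s.",
        what, paste0('"', allowed, '"', collapse = ", "),
        paste0('"', as.character(value), '"', collapse = ", ")
      ),
      class = "boostercost_validation_error"
    )
  }
  value
}
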