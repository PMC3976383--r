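`%||%` <- function(x, y) if (is.null(x)) y else x

#' Round half away from zero
#'
#' Fixed-decimal rounding with ties going up (56.25 -> 56.3), as used for all
#' reported percentages. `base::round()` rounds half to even and would print
#' 56.2 instead.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

STATUS_LEVELS <- c("case", "control", "obligate_carrier", "unknown")

## PED status-code dialect: 1=control, 2=case, 3=obligate carrier, 0=unknown
status_from_code <- function(code) {
  out <- rep(NA_character_, length(code))
  out[code == 1] <- "control"
  out[code == 2] <- "case"
  out[code == 3] <- "obligate_carrier"
  out[code == 0] <- "unknown"
  if (anyNA(out)) stopf("unknown status code(s): %s",
                        paste(unique(code[is.na(out)]), collapse = ", "))
  out
}

status_to_code <- function(status) {
  unname(c(control = 1L, case = 2L, obligate_carrier = 3L, unknown = 0L)[status])
}
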