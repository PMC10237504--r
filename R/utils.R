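#' Round half away from zero
#'
#' Base `round()` uses round-half-to-even; the report tables in this package
#' use conventional half-up rounding (0.7925 -> 0.793 at 3 digits).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + 1e-12) / m
}

#' Truncate toward zero at a number of decimals
#'
#' @param x numeric vector.
#' @param digits decimal places kept.
#' @return truncated numeric vector.
#' @export
trunc_toward_zero <- function(x, digits = 0) {
  m <- 10^digits
  trunc(x * m + sign(x) * 1e-12) / m
}

# Deterministic per-repetition seed from a master seed, kept inside 32-bit
# integer range.
derive_seed <- function(master, i) {
  as.integer((as.numeric(master) + as.numeric(i)) %% (2^31 - 1))
}

clip01 <- function(p, eps = 1e-6) pmin(pmax(p, eps), 1 - eps)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_missing <- function(df, fields, context = "record") {
  for (f in fields) {
    if (!f %in% names(df)) {
      stop(sprintf("%s is missing required field '%s'", context, f),
           call. = FALSE)
    }
    if (anyNA(df[[f]])) {
      stop(sprintf("%s has missing values in required field '%s'", context, f),
           call. = FALSE)
    }
  }
  invisible(TRUE)
}
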