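# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Decimal rounding that always carries a trailing 5 upward in absolute
#' value, matching how survey report tables are typically rounded
#' (base `round()` rounds half to even). A small epsilon guards against
#' binary representation of decimal halves.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 0).
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

# stopifnot-style check with a formatted message
check_that <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) stop(sprintf(fmt, ...), call. = FALSE)
  invisible(TRUE)
}

check_prob <- function(x, name) {
  check_that(is.numeric(x) && all(is.finite(x)) && all(x >= 0 & x <= 1),
             "`%s` must be a proportion in [0, 1]", name)
}

check_pct <- function(x, name, na_ok = FALSE) {
  ok <- is.numeric(x) && (na_ok || !anyNA(x)) &&
    all(x[!is.na(x)] >= 0 & x[!is.na(x)] <= 100)
  check_that(ok, "`%s` must be a coverage percentage in [0, 100]", name)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
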