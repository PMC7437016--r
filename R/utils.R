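#' Round half away from zero
#'
#' Decimal rounding in which ties are rounded away from zero (the convention
#' used by most clinical papers and by SPSS), unlike [base::round()], which
#' rounds half to even. `round_half_up(0.5) == 1`, `round_half_up(-1.55, 1) ==
#' -1.6`.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (non-negative integer).
#' @return numeric vector of the same length as `x`.
#' @export
round_half_up <- function(x, digits = 0) {
  stopifnot(is.numeric(x), length(digits) == 1L, digits >= 0)
  p <- 10^digits
  # tiny nudge guards against 0.49999999... binary representations of exact ties
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# shortest decimal string that parses back to exactly the same double
format_exact <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return(NA_character_)
    for (d in c(15L, 16L, 17L)) {
      s <- sprintf(paste0("%.", d, "g"), v)
      if (as.numeric(s) == v) return(s)
    }
    sprintf("%.17g", v)
  }, character(1))
}

stop2 <- function(...) stop(..., call. = FALSE)
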