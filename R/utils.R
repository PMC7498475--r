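#' Round half away from zero to a fixed number of decimals
#'
#' Percentage cells in the summary tables are rounded half-up (26.755 -> 26.76)
#' rather than with banker's rounding as [base::round()] does. A tiny epsilon
#' absorbs binary floating-point representation error just below .5 boundaries.
#'
#' @param x numeric vector.
#' @param places integer number of decimal places.
#' @return numeric vector rounded half-up.
#' @export
#' @examples
#' round_half_up(100 * 19 / 71, 2)  # 26.76
round_half_up <- function(x, places = 2) {
  stopifnot(is.numeric(x), places >= 0)
  f <- 10^places
  sign(x) * floor(abs(x) * f + 0.5 + 1e-9) / f
}

# shared logging: level-tagged messages, silenced via option(taxaudit.quiet)
ta_log <- function(fmt, ..., level = "INFO") {
  if (isTRUE(getOption("taxaudit.quiet", FALSE))) return(invisible(NULL))
  message(sprintf("[%s] %s", level, sprintf(fmt, ...)))
}

ta_warn <- function(fmt, ...) ta_log(fmt, ..., level = "WARN")
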