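`%||%` <- function(x, y) if (is.null(x)) y else x

#' Stop with a file-format error naming file and line
#' @noRd
format_error <- function(path, line, msg) {
  stop(sprintf("format error in '%s' (line %d): %s", path, line, msg),
       call. = FALSE)
}

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && !is.na(x) && x >= 0 && x == floor(x)
}

#' Round half up to a fixed number of decimals
#'
#' Base `round()` rounds half to even; printed interval sizes use the
#' conventional half-up rule so 3.534378 Mb renders as 3.53 and 1.005 as 1.01.
#' @noRd
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}
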