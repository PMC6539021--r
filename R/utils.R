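#' Round half away from zero
#'
#' Percentages in reports are rendered at a fixed number of decimals with
#' halves rounded up (so 92.475 renders as 92.48, 7.145 as 7.15), unlike
#' [base::round()]'s round-half-even. Internal arithmetic is always kept in
#' full precision; this is a rendering convention only.
#'
#' @param x numeric vector
#' @param digits decimal places (default 2)
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# scalar NA check that tolerates NULL and zero-length
is_blank <- function(x) {
  is.null(x) || length(x) == 0 || (length(x) == 1 && (is.na(x) || identical(x, "")))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
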