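#' Round half away from zero
#'
#' Decimal rounding in which ties go away from zero (`0.2495 -> 0.250` at 3
#' decimals), matching how agreement tables are conventionally typeset.
#' Base [round()] uses round-half-to-even and would print `0.2495` as
#' `0.249`/`0.25` depending on binary representation.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 0).
#' @return numeric vector, rounded.
#' @export
#' @examples
#' round_half_away(0.2495, 3)
#' round_half_away(75.675, 1)
round_half_away <- function(x, digits = 0) {
  stopifnot(is.numeric(x), length(digits) == 1L, digits >= 0)
  p <- 10^digits
  # tiny nudge absorbs binary-representation error below the rounding scale
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

#' Normalize chromosome labels
#'
#' Maps the chromosome naming conventions found in manifests, SNP tables and
#' tool outputs onto one alphabet: `1`-`22`, `X`, `Y`, `MT`. Strips a leading
#' `chr` prefix, uppercases, and maps the numeric aliases `23 -> X`,
#' `24 -> Y`, `26 -> MT` and `M -> MT`.
#'
#' @param x character (or coercible) vector of chromosome labels.
#' @return character vector of normalized labels; labels outside the alphabet
#'   are returned unchanged (validation happens at parse time).
#' @export
#' @examples
#' normalize_chrom(c("chr7", "x", "23", "M"))
normalize_chrom <- function(x) {
  x <- toupper(trimws(as.character(x)))
  x <- sub("^CHR", "", x)
  x[x == "23"] <- "X"
  x[x == "24"] <- "Y"
  x[x %in% c("26", "M")] <- "MT"
  x
}

chrom_alphabet <- function() c(as.character(1:22), "X", "Y", "MT")

# Errors carry classes so the CLI can map them to exit codes
# (2 = configuration, 3 = validation).
config_error <- function(msg, ...) {
  rlang::abort(msg, class = "chipconcord_config_error", ...)
}

validation_error <- function(msg, ...) {
  rlang::abort(msg, class = "chipconcord_validation_error", ...)
}

`%||%` <- rlang::`%||%`
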