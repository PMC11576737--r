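#' Canonical variant key
#'
#' Builds the `chrom:pos:ref:alt` string used to join genotype, annotation
#' and classification tables. Keys are only comparable for variants in
#' minimal (normalized) representation.
#'
#' @param chrom Chromosome name(s).
#' @param pos 1-based position(s).
#' @param ref,alt Allele strings.
#' @return Character vector of keys.
#' @export
variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Base `round()` rounds half to even; clinical summary tables here use
#' conventional half-up rounding so that e.g. 42.5 prints as 43.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Format a proportion as a percentage value
#'
#' @param x Proportion(s) in \[0, 1\].
#' @param digits Decimal places of the percentage.
#' @param mode `"round"` (half-up, the default used in summary tables) or
#'   `"truncate"` (drop trailing digits). Both conventions occur in
#'   published cohort tables, so the choice is configurable.
#' @return Numeric percentage values (e.g. 0.0354 -> 3.5).
#' @export
format_percent <- function(x, digits = 1, mode = c("round", "truncate")) {
  mode <- match.arg(mode)
  pct <- 100 * x
  if (mode == "round") round_half_up(pct, digits) else trunc(pct * 10^digits) / 10^digits
}

# Internal structured log: a growing data.frame of (stage, detail, n).
new_log <- function() {
  env <- new.env(parent = emptyenv())
  env$entries <- data.frame(stage = character(), detail = character(),
                            n = integer(), stringsAsFactors = FALSE)
  env
}

log_add <- function(log, stage, detail, n = NA_integer_) {
  if (is.null(log)) return(invisible(NULL))
  log$entries <- rbind(log$entries, data.frame(
    stage = stage, detail = detail, n = as.integer(n),
    stringsAsFactors = FALSE))
  invisible(NULL)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
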