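#' @keywords internal
"_PACKAGE"

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Chromosome universe used throughout the package
#'
#' Autosomes plus chrX and chrY, in karyotype order. Per-chromosome scores
#' are computed over this universe; chromosomes outside it are still scored
#' if present in the input, sorted after chrY.
#'
#' @return Character vector of 24 chromosome names.
#' @export
default_chromosomes <- function() {
  c(paste0("chr", 1:22), "chrX", "chrY")
}

#' Toy genome: chromosome lengths in base pairs
#'
#' Approximate human (hg19-scale) chromosome lengths, rounded to the nearest
#' megabase. Used by the synthetic-data generator to place variants and
#' segments; the concordance statistics themselves never need a genome.
#'
#' @return Named integer vector (chromosome -> length in bp).
#' @export
default_genome <- function() {
  mb <- c(249, 243, 198, 191, 181, 171, 159, 146, 141, 136, 135, 134,
          115, 107, 103, 90, 81, 78, 59, 63, 48, 51, 155, 59)
  stats::setNames(as.integer(mb * 1e6), default_chromosomes())
}

# karyotype sort for chromosome names; unknown names go last, alphabetically
sort_chromosomes <- function(chroms) {
  universe <- default_chromosomes()
  known <- chroms[chroms %in% universe]
  unknown <- sort(unique(chroms[!chroms %in% universe]))
  c(universe[universe %in% known], unknown)
}

# internal: stop with sprintf-style message
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# internal: warn with sprintf-style message
warn <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
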