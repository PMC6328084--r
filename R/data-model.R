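#' Construct a table of somatic variant calls
#'
#' The internal representation of simple somatic mutations (SSM): one row
#' per call, 1-based positions, one annotation category per call. Two calls
#' are the *same* variant iff they share chromosome, position, reference and
#' alternate allele; the annotation category and read depths are not part of
#' variant identity.
#'
#' @param chrom Character vector of chromosome names.
#' @param pos Integer vector of 1-based positions.
#' @param ref,alt Character vectors of reference/alternate alleles
#'   (non-empty, must differ position-wise).
#' @param mutation_type Character vector of annotation-category labels
#'   (e.g. "Missense_Mutation", "lincRNA").
#' @param ref_depth,alt_depth Optional non-negative integer read depths
#'   supporting the reference/alternate allele (NA when unavailable).
#' @param sample_id Sample identifier (recycled).
#' @return A `data.frame` with class `variant_calls`.
#' @export
variant_calls <- function(chrom = character(), pos = integer(),
                          ref = character(), alt = character(),
                          mutation_type = character(),
                          ref_depth = NA_integer_, alt_depth = NA_integer_,
                          sample_id = NA_character_) {
  n <- max(length(chrom), length(pos), length(ref), length(alt),
           length(mutation_type) * (length(chrom) > 0))
  df <- data.frame(
    chrom = rep_len(as.character(chrom), n),
    pos = rep_len(as.integer(pos), n),
    ref = rep_len(as.character(ref), n),
    alt = rep_len(as.character(alt), n),
    mutation_type = rep_len(as.character(mutation_type %||% "Unannotated"),
                            n),
    ref_depth = rep_len(as.integer(ref_depth), n),
    alt_depth = rep_len(as.integer(alt_depth), n),
    sample_id = rep_len(as.character(sample_id), n),
    stringsAsFactors = FALSE
  )
  validate_variant_calls(df)
  class(df) <- c("variant_calls", "data.frame")
  df
}

validate_variant_calls <- function(df) {
  if (nrow(df) == 0) return(invisible(df))
  if (any(df$pos < 1)) abort("variant positions must be >= 1")
  if (any(!nzchar(df$ref)) || any(!nzchar(df$alt)))
    abort("ref and alt alleles must be non-empty")
  if (any(df$ref == df$alt))
    abort("ref and alt alleles must differ")
  bad <- c(df$ref_depth, df$alt_depth)
  if (any(bad < 0, na.rm = TRUE)) abort("read depths must be non-negative")
  invisible(df)
}

sv_categories <- c("DEL", "DUP", "INV", "TRA")

#' Construct a table of structural-variant events
#'
#' One row per SV event, defined by a breakpoint pair and a category.
#' Deletions, duplications and inversions are intra-chromosomal
#' (`chrom_a == chrom_b`, `pos_a < pos_b`); translocations join two
#' different chromosomes. Positions are 1-based point breakpoints.
#'
#' @param chrom_a,pos_a First breakpoint.
#' @param chrom_b,pos_b Second breakpoint.
#' @param category One of "DEL", "DUP", "INV", "TRA" per event.
#' @param sample_id Sample identifier (recycled).
#' @return A `data.frame` with class `sv_events`.
#' @export
sv_events <- function(chrom_a = character(), pos_a = integer(),
                      chrom_b = character(), pos_b = integer(),
                      category = character(), sample_id = NA_character_) {
  n <- max(length(chrom_a), length(pos_a), length(chrom_b), length(pos_b),
           length(category))
  if (min(length(chrom_a), length(pos_a), length(chrom_b), length(pos_b),
          length(category)) == 0) n <- 0L
  df <- data.frame(
    chrom_a = rep_len(as.character(chrom_a), n),
    pos_a = rep_len(as.integer(pos_a), n),
    chrom_b = rep_len(as.character(chrom_b), n),
    pos_b = rep_len(as.integer(pos_b), n),
    category = rep_len(as.character(category), n),
    sample_id = rep_len(as.character(sample_id), n),
    stringsAsFactors = FALSE
  )
  validate_sv_events(df)
  class(df) <- c("sv_events", "data.frame")
  df
}

validate_sv_events <- function(df) {
  if (nrow(df) == 0) return(invisible(df))
  bad_cat <- setdiff(unique(df$category), sv_categories)
  if (length(bad_cat))
    abort("unknown SV category: %s", paste(bad_cat, collapse = ", "))
  intra <- df$category != "TRA"
  if (any(intra & df$chrom_a != df$chrom_b))
    abort("DEL/DUP/INV events must be intra-chromosomal")
  if (any(intra & df$pos_a >= df$pos_b))
    abort("intra-chromosomal events require pos_a < pos_b")
  if (any(!intra & df$chrom_a == df$chrom_b))
    abort("TRA events must join two different chromosomes")
  invisible(df)
}

#' Construct a table of copy-number segments
#'
#' Segments carry an average integer copy number (`imean`) over a 0-based
#' half-open genomic interval. `imean` may be NA (segment present but copy
#' number undefined); such bases are excluded from defined-base totals in
#' concordance scoring.
#'
#' @param chrom Chromosome names.
#' @param start,end 0-based half-open interval bounds (`start < end`).
#' @param imean Average integer copy number per segment (non-negative, NA
#'   allowed).
#' @param sample_id Sample identifier (recycled).
#' @return A `data.frame` with class `cn_segments`.
#' @export
cn_segments <- function(chrom = character(), start = integer(),
                        end = integer(), imean = numeric(),
                        sample_id = NA_character_) {
  n <- max(length(chrom), length(start), length(end))
  if (min(length(chrom), length(start), length(end)) == 0) n <- 0L
  df <- data.frame(
    chrom = rep_len(as.character(chrom), n),
    start = rep_len(as.numeric(start), n),
    end = rep_len(as.numeric(end), n),
    imean = rep_len(as.numeric(imean), n),
    sample_id = rep_len(as.character(sample_id), n),
    stringsAsFactors = FALSE
  )
  validate_cn_segments(df)
  class(df) <- c("cn_segments", "data.frame")
  df
}

validate_cn_segments <- function(df) {
  if (nrow(df) == 0) return(invisible(df))
  if (any(df$start >= df$end)) abort("segments require start < end")
  if (any(df$imean < 0, na.rm = TRUE)) abort("imean must be non-negative")
  invisible(df)
}

#' Per-sample ploidy record
#'
#' @param sample_id Sample identifier.
#' @param ploidy Genome-average copy number (> 0).
#' @param normal_fraction,tumour_fraction Optional cellularity estimates in
#'   \[0, 1\].
#' @return A list with class `sample_ploidy`.
#' @export
sample_ploidy <- function(sample_id, ploidy, normal_fraction = NA_real_,
                          tumour_fraction = NA_real_) {
  ploidy <- as.numeric(ploidy)
  if (!is.finite(ploidy) || ploidy <= 0)
    abort("ploidy must be a positive number, got %s", format(ploidy))
  structure(
    list(sample_id = as.character(sample_id), ploidy = ploidy,
         normal_fraction = as.numeric(normal_fraction),
         tumour_fraction = as.numeric(tumour_fraction)),
    class = "sample_ploidy"
  )
}

# coerce a sample_ploidy or bare number to a positive scalar ploidy
as_ploidy <- function(x) {
  p <- if (inherits(x, "sample_ploidy")) x$ploidy else as.numeric(x)
  if (length(p) != 1 || !is.finite(p) || p <= 0)
    abort("ploidy must be a single positive number")
  p
}
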