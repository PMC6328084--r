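# accepted spellings for SV categories (case-insensitive)
sv_category_synonyms <- c(
  DEL = "DEL", DELETION = "DEL",
  DUP = "DUP", DUPLICATION = "DUP", ITX = "DUP",
  INV = "INV", INVERSION = "INV",
  TRA = "TRA", TRANSLOCATION = "TRA", CTX = "TRA", BND = "TRA"
)

normalize_sv_category <- function(x, context = "") {
  out <- sv_category_synonyms[toupper(x)]
  if (anyNA(out)) {
    bad <- which(is.na(out))[1]
    abort("unknown SV category '%s'%s", x[bad],
          if (nzchar(context)) paste0(" (", context, " line ", bad, ")") else "")
  }
  unname(out)
}

#' Read structural-variant events from a BEDPE file
#'
#' Expects the 10 standard BEDPE columns (chrom1, start1, end1, chrom2,
#' start2, end2, name, score, strand1, strand2) followed by an 11th column
#' carrying the SV category. BEDPE coordinates are 0-based half-open; point
#' breakpoints are taken as `start + 1` (1-based). Category labels are
#' normalized case-insensitively ("deletion" -> DEL, etc.). Intra-chromosomal
#' events are reordered so the lower breakpoint comes first.
#'
#' @param path Path to a BEDPE file (optionally with `#`-comment header).
#' @param sample_id Sample identifier to stamp on every event.
#' @return An `sv_events` data.frame.
#' @export
read_sv_bedpe <- function(path, sample_id) {
  if (!file.exists(path)) abort("BEDPE file not found: %s", path)
  raw <- tryCatch(
    utils::read.table(path, sep = "\t", header = FALSE,
                      comment.char = "#", stringsAsFactors = FALSE,
                      colClasses = "character"),
    error = function(e) NULL  # empty file / comments only
  )
  if (is.null(raw) || nrow(raw) == 0) return(sv_events(sample_id = sample_id))
  if (ncol(raw) < 11)
    abort("BEDPE needs 11 columns (10 standard + svtype), got %d", ncol(raw))
  cat <- normalize_sv_category(raw[[11]], context = basename(path))
  pos_a <- as.integer(raw[[2]]) + 1L
  pos_b <- as.integer(raw[[5]]) + 1L
  chrom_a <- raw[[1]]
  chrom_b <- raw[[4]]
  # canonical breakpoint order within a chromosome
  flip <- chrom_a == chrom_b & pos_a > pos_b
  if (any(flip)) {
    tmp <- pos_a[flip]; pos_a[flip] <- pos_b[flip]; pos_b[flip] <- tmp
  }
  sv_events(chrom_a, pos_a, chrom_b, pos_b, cat, sample_id = sample_id)
}

#' Write structural-variant events to a BEDPE file
#'
#' Inverse of [read_sv_bedpe()]: 1-based point breakpoints become 0-based
#' half-open single-base intervals, and the category goes in column 11.
#'
#' @param events An `sv_events` table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sv_bedpe <- function(events, path) {
  if (nrow(events) > 0) {
    ord <- order(match(events$chrom_a, sort_chromosomes(events$chrom_a)),
                 events$pos_a, events$pos_b)
    events <- events[ord, , drop = FALSE]
    lines <- paste(events$chrom_a, events$pos_a - 1L, events$pos_a,
                   events$chrom_b, events$pos_b - 1L, events$pos_b,
                   ".", ".", "+", "-", events$category, sep = "\t")
  } else {
    lines <- character()
  }
  writeLines(lines, path)
  invisible(path)
}
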