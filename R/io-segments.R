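#' Read copy-number segments plus a sample ploidy
#'
#' Parses a tab-separated segment table with header
#' `chrom start end imean` (0-based half-open intervals; `imean` may be
#' empty/NA for segments with undefined copy number). The sample's ploidy —
#' required for rescaling — is taken from a `#ploidy=<value>` header line in
#' the segment file, or, failing that, from a side-car ploidy table (see
#' [read_ploidy_table()]). If neither supplies it, this is a hard error.
#'
#' Segments are sorted; overlapping segments within the sample are treated
#' as an input defect and resolved deterministically by truncating the
#' earlier segment at the later segment's start (with a warning).
#'
#' @param path Path to the segment file.
#' @param sample_id Sample identifier.
#' @param ploidy Optional ploidy value overriding any header/side-car.
#' @param ploidy_path Optional path to a ploidy side-car table.
#' @return A list with elements `segments` (`cn_segments`) and `ploidy`
#'   (`sample_ploidy`).
#' @export
read_cn_segments <- function(path, sample_id, ploidy = NULL,
                             ploidy_path = NULL) {
  if (!file.exists(path)) abort("segment file not found: %s", path)
  header_lines <- grep("^#", readLines(path, n = 20L), value = TRUE)
  pl <- ploidy
  nf <- NA_real_
  tf <- NA_real_
  if (is.null(pl)) {
    m <- regmatches(header_lines,
                    regexpr("(?<=^#ploidy=)[0-9.eE+-]+", header_lines,
                            perl = TRUE))
    m <- unlist(m)
    if (length(m) >= 1) pl <- as.numeric(m[1])
  }
  if (is.null(pl) && !is.null(ploidy_path)) {
    tab <- read_ploidy_table(ploidy_path)
    hit <- tab[tab$sample_id == sample_id, , drop = FALSE]
    if (nrow(hit) == 1) {
      pl <- hit$ploidy
      nf <- hit$normal_fraction; tf <- hit$tumour_fraction
    }
  }
  if (is.null(pl))
    abort("no ploidy available for sample '%s' (required for rescaling)",
          sample_id)

  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          comment.char = "#", stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  need <- c("chrom", "start", "end", "imean")
  if (!all(need %in% names(df)))
    abort("segment file %s lacks columns: %s", basename(path),
          paste(setdiff(need, names(df)), collapse = ", "))
  segs <- resolve_segment_overlaps(df, basename(path))
  list(
    segments = cn_segments(segs$chrom, segs$start, segs$end, segs$imean,
                           sample_id = sample_id),
    ploidy = sample_ploidy(sample_id, pl, nf, tf)
  )
}

# sort per chromosome; truncate any segment that overlaps its successor
resolve_segment_overlaps <- function(df, label = "") {
  df <- df[order(match(df$chrom, sort_chromosomes(df$chrom)), df$start,
                 df$end), , drop = FALSE]
  n_trunc <- 0L
  for (chrom in unique(df$chrom)) {
    i <- which(df$chrom == chrom)
    if (length(i) < 2) next
    for (k in seq_len(length(i) - 1L)) {
      if (df$end[i[k]] > df$start[i[k + 1L]]) {
        df$end[i[k]] <- df$start[i[k + 1L]]
        n_trunc <- n_trunc + 1L
      }
    }
  }
  if (n_trunc > 0)
    warn("%d overlapping segment(s) in %s truncated at successor start",
         n_trunc, label)
  df <- df[df$start < df$end, , drop = FALSE]
  df
}

#' Write copy-number segments with an embedded ploidy header
#'
#' Inverse of [read_cn_segments()]: writes `#ploidy=<value>` followed by a
#' `chrom start end imean` tab-separated table. `imean` is printed with six
#' decimal places; NA is written as "NA".
#'
#' @param segments A `cn_segments` table.
#' @param ploidy A `sample_ploidy` or a bare positive number.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cn_segments <- function(segments, ploidy, path) {
  pl <- as_ploidy(ploidy)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#ploidy=%.6g", pl), con)
  writeLines("chrom\tstart\tend\timean", con)
  if (nrow(segments) > 0) {
    ord <- order(match(segments$chrom, sort_chromosomes(segments$chrom)),
                 segments$start)
    segments <- segments[ord, , drop = FALSE]
    writeLines(paste(segments$chrom,
                     format(segments$start, scientific = FALSE, trim = TRUE),
                     format(segments$end, scientific = FALSE, trim = TRUE),
                     ifelse(is.na(segments$imean), "NA",
                            sprintf("%.6f", segments$imean)),
                     sep = "\t"), con)
  }
  invisible(path)
}

#' Read a ploidy side-car table
#'
#' Tab-separated with header
#' `sample_id ploidy normal_fraction tumour_fraction` (the last two
#' optional).
#'
#' @param path Path to the table.
#' @return A data.frame with one row per sample.
#' @export
read_ploidy_table <- function(path) {
  if (!file.exists(path)) abort("ploidy table not found: %s", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  if (!all(c("sample_id", "ploidy") %in% names(df)))
    abort("ploidy table needs columns sample_id and ploidy")
  if (is.null(df$normal_fraction)) df$normal_fraction <- NA_real_
  if (is.null(df$tumour_fraction)) df$tumour_fraction <- NA_real_
  df
}

#' Write a ploidy side-car table
#'
#' @param ploidies A list of `sample_ploidy` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ploidy_table <- function(ploidies, path) {
  if (inherits(ploidies, "sample_ploidy")) ploidies <- list(ploidies)
  df <- do.call(rbind, lapply(ploidies, function(p) {
    data.frame(sample_id = p$sample_id, ploidy = p$ploidy,
               normal_fraction = p$normal_fraction,
               tumour_fraction = p$tumour_fraction,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}
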