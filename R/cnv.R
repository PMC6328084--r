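#' Rescale segment copy numbers by sample ploidy
#'
#' Divides every defined `imean` by the sample's genome-average ploidy, so a
#' segment at the sample's average level sits at 1 regardless of
#' whole-genome doubling. Missing values stay missing; coordinates are
#' untouched.
#'
#' @param segments A `cn_segments` table.
#' @param ploidy A `sample_ploidy` object or a bare positive number.
#' @return The segments with `imean` replaced by the rescaled value.
#' @export
rescale_by_ploidy <- function(segments, ploidy) {
  p <- as_ploidy(ploidy)
  segments$imean <- segments$imean / p
  segments
}

#' Partition two segment profiles into constant-value overlap blocks
#'
#' Splits the union footprint of two samples' segmentations, per
#' chromosome, into maximal blocks on which each sample's (rescaled) copy
#' number is constant — present with a value, present with NA, or absent.
#' Blocks covered by neither sample are omitted, so per chromosome the
#' total block length equals the length of the union of the two samples'
#' segment footprints. Interval arithmetic is delegated to IRanges
#' (disjoin + overlap lookup), the in-memory equivalent of a bedtools
#' intersection.
#'
#' @param a_segments,b_segments `cn_segments` tables (per-sample
#'   non-overlapping; run through [read_cn_segments()] or equivalent).
#' @param tolerance Copy-state agreement tolerance used to populate the
#'   `agrees` column (default 0.25).
#' @return A data.frame of blocks: chrom, start, end (0-based half-open),
#'   value_a, value_b (NA when absent/undefined), agrees (both defined and
#'   differing by at most `tolerance`).
#' @export
intersect_segments <- function(a_segments, b_segments, tolerance = 0.25) {
  chroms <- sort_chromosomes(unique(c(a_segments$chrom, b_segments$chrom)))
  out <- lapply(chroms, function(ch) {
    a <- a_segments[a_segments$chrom == ch, , drop = FALSE]
    b <- b_segments[b_segments$chrom == ch, , drop = FALSE]
    # 0-based half-open [start,end) -> IRanges 1-based closed [start+1, end]
    ra <- IRanges::IRanges(start = a$start + 1, end = a$end)
    rb <- IRanges::IRanges(start = b$start + 1, end = b$end)
    blocks <- IRanges::disjoin(c(ra, rb))
    if (length(blocks) == 0) return(NULL)
    hit_a <- IRanges::findOverlaps(blocks, ra, type = "within",
                                   select = "first")
    hit_b <- IRanges::findOverlaps(blocks, rb, type = "within",
                                   select = "first")
    data.frame(
      chrom = ch,
      start = IRanges::start(blocks) - 1,
      end = IRanges::end(blocks),
      value_a = ifelse(is.na(hit_a), NA_real_, a$imean[hit_a]),
      value_b = ifelse(is.na(hit_b), NA_real_, b$imean[hit_b]),
      covered_a = !is.na(hit_a), covered_b = !is.na(hit_b),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, Filter(Negate(is.null), out))
  if (is.null(out))
    out <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), value_a = numeric(),
                      value_b = numeric(), covered_a = logical(),
                      covered_b = logical(), stringsAsFactors = FALSE)
  out$agrees <- !is.na(out$value_a) & !is.na(out$value_b) &
    abs(out$value_a - out$value_b) <= tolerance
  rownames(out) <- NULL
  out
}

cn_concordance_row <- function(blocks, tolerance, scope) {
  len <- blocks$end - blocks$start
  def_a <- !is.na(blocks$value_a)
  def_b <- !is.na(blocks$value_b)
  t_bases <- sum(len[def_a])
  m_bases <- sum(len[def_b])
  union_bases <- sum(len[def_a | def_b])
  agree <- def_a & def_b & abs(blocks$value_a - blocks$value_b) <= tolerance
  agree_bases <- sum(len[agree])
  data.frame(scope = scope, t_bases = t_bases, m_bases = m_bases,
             union_bases = union_bases, agree_bases = agree_bases,
             stringsAsFactors = FALSE)
}

#' Base-weighted copy-number concordance score
#'
#' Over the overlap blocks of a pair: T = bases where sample A has a
#' defined (rescaled) copy number, X = likewise for sample B, C = bases
#' where either is defined, and I = bases where both are defined and the
#' values differ by at most `tolerance` (default 0.25). The score is
#' G = I / (T + X - C); since T + X - C is exactly the co-defined
#' footprint, G is the fraction of co-defined bases in agreement.
#' `denominator = "union"` scores I / C instead (agreement over all defined
#' bases). The score is NA when the denominator is 0.
#'
#' @param blocks Overlap blocks from [intersect_segments()] (values already
#'   ploidy-rescaled if ploidy correction is wanted).
#' @param tolerance Maximum absolute copy-state difference counted as
#'   agreement (default 0.25).
#' @param scope "genome" (all blocks) or a chromosome name.
#' @param denominator "codefined" (the literal T + X - C) or "union" (C).
#' @return A one-row data.frame: scope, t_bases, m_bases, union_bases,
#'   agree_bases, score.
#' @export
cn_concordance <- function(blocks, tolerance = 0.25, scope = "genome",
                           denominator = c("codefined", "union")) {
  denominator <- match.arg(denominator)
  if (!identical(scope, "genome"))
    blocks <- blocks[blocks$chrom == scope, , drop = FALSE]
  row <- cn_concordance_row(blocks, tolerance, scope)
  denom <- if (denominator == "codefined")
    row$t_bases + row$m_bases - row$union_bases else row$union_bases
  row$score <- if (denom > 0) row$agree_bases / denom else NA_real_
  row
}

#' Copy-number concordance per chromosome plus genome-wide
#'
#' Convenience wrapper over [cn_concordance()]: one row per chromosome
#' present in the blocks, plus a "genome" row aggregating the per-chromosome
#' numerators and denominators (not the mean of the per-chromosome scores).
#'
#' @inheritParams cn_concordance
#' @return A data.frame of concordance rows, "genome" first.
#' @export
cn_concordance_table <- function(blocks, tolerance = 0.25,
                                 denominator = c("codefined", "union")) {
  denominator <- match.arg(denominator)
  scopes <- c("genome", sort_chromosomes(unique(blocks$chrom)))
  out <- do.call(rbind, lapply(scopes, function(s) {
    cn_concordance(blocks, tolerance = tolerance, scope = s,
                   denominator = denominator)
  }))
  rownames(out) <- NULL
  out
}

#' Classify a pair's ploidy relationship
#'
#' Compares two samples' ploidy estimates: "comparable" when the ratio of
#' larger to smaller is within `rel_tol` of 1, "doubled" when within
#' `rel_tol` of 2 (whole-genome doubling in one sample), otherwise
#' "ambiguous". Scoring still proceeds on rescaled values either way; the
#' flag is reported so ambiguous pairs can be excluded downstream.
#'
#' @param t_ploidy,m_ploidy `sample_ploidy` objects or positive numbers.
#' @param rel_tol Relative tolerance on the ploidy ratio (default 0.1).
#' @return One of "comparable", "doubled", "ambiguous".
#' @export
ploidy_qc <- function(t_ploidy, m_ploidy, rel_tol = 0.1) {
  p1 <- as_ploidy(t_ploidy); p2 <- as_ploidy(m_ploidy)
  ratio <- max(p1, p2) / min(p1, p2)
  if (abs(ratio - 1) <= rel_tol) return("comparable")
  if (abs(ratio - 2) <= 2 * rel_tol) return("doubled")
  "ambiguous"
}
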