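#' Variant identity keys
#'
#' Two somatic calls denote the same variant iff they share chromosome,
#' 1-based position, reference allele and alternate allele. Annotation
#' category and read depths are deliberately excluded from identity: a
#' variant relabelled by annotation is still the same substitution.
#'
#' @param calls A `variant_calls` table.
#' @return A character vector of opaque identity keys, one per call.
#' @export
variant_identity_key <- function(calls) {
  if (nrow(calls) == 0) return(character())
  paste(calls$chrom, calls$pos, calls$ref, calls$alt, sep = "\r")
}

# Jaccard over two key sets; NA when both empty
key_jaccard_row <- function(type, t_keys, m_keys) {
  t_keys <- unique(t_keys)
  m_keys <- unique(m_keys)
  shared <- length(intersect(t_keys, m_keys))
  tn <- length(t_keys)
  mn <- length(m_keys)
  denom <- tn + mn - shared
  data.frame(
    mutation_type = type, t_count = tn, m_count = mn, shared = shared,
    jaccard = if (denom > 0) shared / denom else NA_real_,
    stringsAsFactors = FALSE
  )
}

#' Per-category mutation Jaccard indices
#'
#' For each annotation category M present in either sample, computes
#' J_M = C_M / (T_M + P_M - C_M), where T_M and P_M are the numbers of
#' distinct variants of category M in the tumour and the model, and C_M the
#' number of identical variants (same chromosome, position and
#' substitution) annotated M in both. Duplicate identity keys within one
#' sample collapse before counting (set semantics). A category absent from
#' both samples is never emitted; the Jaccard is NA only in the degenerate
#' all-empty call.
#'
#' @param tumour_calls,model_calls `variant_calls` tables for the two
#'   samples of one patient.
#' @return A data.frame with columns mutation_type, t_count, m_count,
#'   shared, jaccard — one row per category, sorted by category.
#' @export
jaccard_by_type <- function(tumour_calls, model_calls) {
  t_keys <- variant_identity_key(tumour_calls)
  m_keys <- variant_identity_key(model_calls)
  types <- sort(unique(c(tumour_calls$mutation_type,
                         model_calls$mutation_type)))
  rows <- lapply(types, function(ty) {
    key_jaccard_row(ty,
                    t_keys[tumour_calls$mutation_type == ty],
                    m_keys[model_calls$mutation_type == ty])
  })
  if (length(rows) == 0)
    return(data.frame(mutation_type = character(), t_count = integer(),
                      m_count = integer(), shared = integer(),
                      jaccard = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Overall mutation Jaccard across all categories
#'
#' One Jaccard over the union of every variant regardless of category
#' (reported as category "All Mutations"). With both samples empty the
#' Jaccard is NA with zero counts.
#'
#' @inheritParams jaccard_by_type
#' @param snv_only If TRUE, restrict to single-nucleotide substitutions
#'   (1-bp ref and alt) before scoring.
#' @return A one-row data.frame in the same shape as [jaccard_by_type()].
#' @export
jaccard_all_mutations <- function(tumour_calls, model_calls,
                                  snv_only = FALSE) {
  if (snv_only) {
    tumour_calls <- tumour_calls[nchar(tumour_calls$ref) == 1 &
                                   nchar(tumour_calls$alt) == 1, ,
                                 drop = FALSE]
    model_calls <- model_calls[nchar(model_calls$ref) == 1 &
                                 nchar(model_calls$alt) == 1, , drop = FALSE]
  }
  key_jaccard_row("All Mutations",
                  variant_identity_key(tumour_calls),
                  variant_identity_key(model_calls))
}

#' Variant-allele fraction
#'
#' alt_depth / (alt_depth + ref_depth) per call; NA when either depth is
#' missing or both are zero. Descriptive only — VAF feeds no concordance
#' score.
#'
#' @param calls A `variant_calls` table.
#' @return Numeric vector of fractions in \[0, 1\] (NA where undefined).
#' @export
variant_allele_fraction <- function(calls) {
  total <- calls$alt_depth + calls$ref_depth
  ifelse(is.na(total) | total == 0, NA_real_, calls$alt_depth / total)
}

#' Default driver-gene panel
#'
#' Named 1-based inclusive genomic intervals for eight genes recurrently
#' altered in pancreatic ductal adenocarcinoma. Coordinates are approximate
#' hg19 gene spans (rounded outward), adequate for tallying calls placed by
#' the synthetic generator or by any caller using the same assembly.
#'
#' @return A data.frame with columns gene, chrom, start, end.
#' @export
default_driver_panel <- function() {
  data.frame(
    gene  = c("KRAS", "TP53", "CDKN2A", "SMAD4", "TGFB2", "MAP2K4",
              "RNF43", "KDM6A"),
    chrom = c("chr12", "chr17", "chr9", "chr18", "chr1", "chr17",
              "chr17", "chrX"),
    start = c(25357000L, 7565000L, 21967000L, 48556000L, 218518000L,
              11924000L, 56429000L, 44732000L),
    end   = c(25404000L, 7591000L, 21996000L, 48612000L, 218618000L,
              12047000L, 56495000L, 44972000L),
    stringsAsFactors = FALSE
  )
}

#' Tally mutation categories per driver gene and sample
#'
#' For each panel gene and each sample, collects the annotation-category
#' labels of all calls whose position falls inside the gene's 1-based
#' inclusive interval (boundary positions included).
#'
#' @param calls_by_sample Either a single `variant_calls` table covering one
#'   or more `sample_id`s, or a named list of such tables.
#' @param gene_panel A data.frame with columns gene, chrom, start, end
#'   (1-based inclusive); defaults to [default_driver_panel()].
#' @return A character matrix (genes x samples) whose entries are
#'   comma-joined mutation-type labels, `""` when a gene carries no call in
#'   a sample.
#' @export
driver_panel_summary <- function(calls_by_sample,
                                 gene_panel = default_driver_panel()) {
  if (is.data.frame(calls_by_sample)) {
    ids <- unique(calls_by_sample$sample_id)
    calls_by_sample <- lapply(stats::setNames(ids, ids), function(s) {
      calls_by_sample[calls_by_sample$sample_id == s, , drop = FALSE]
    })
  }
  need <- c("gene", "chrom", "start", "end")
  if (!all(need %in% names(gene_panel)))
    abort("gene panel needs columns: %s", paste(need, collapse = ", "))
  if (any(!is.finite(gene_panel$start)) || any(!is.finite(gene_panel$end)) ||
      any(gene_panel$start > gene_panel$end) || any(gene_panel$start < 1))
    abort("malformed gene panel interval")
  out <- matrix("", nrow = nrow(gene_panel), ncol = length(calls_by_sample),
                dimnames = list(gene_panel$gene, names(calls_by_sample)))
  for (s in names(calls_by_sample)) {
    calls <- calls_by_sample[[s]]
    for (g in seq_len(nrow(gene_panel))) {
      hit <- calls$chrom == gene_panel$chrom[g] &
        calls$pos >= gene_panel$start[g] & calls$pos <= gene_panel$end[g]
      if (any(hit))
        out[g, s] <- paste(calls$mutation_type[hit], collapse = ",")
    }
  }
  out
}
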