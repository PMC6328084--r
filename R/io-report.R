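# assemble a rows x pairs score matrix from per-pair named score vectors
score_matrix <- function(per_pair, row_order = NULL) {
  rows <- unique(unlist(lapply(per_pair, names)))
  if (!is.null(row_order))
    rows <- c(intersect(row_order, rows), setdiff(rows, row_order))
  mat <- matrix(NA_real_, nrow = length(rows), ncol = length(per_pair),
                dimnames = list(rows, names(per_pair)))
  for (p in names(per_pair)) {
    v <- per_pair[[p]]
    mat[names(v), p] <- as.numeric(v)
  }
  mat
}

write_score_tsv <- function(mat, path, row_label) {
  ch <- matrix(ifelse(is.na(mat), "NA", sprintf("%.10g", mat)),
               nrow = nrow(mat), dimnames = dimnames(mat))
  df <- data.frame(rownames(mat), ch, stringsAsFactors = FALSE,
                   check.names = FALSE)
  names(df) <- c(row_label, colnames(mat))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a patient's concordance report as TSV matrices
#'
#' Emits one tab-separated matrix per analysis, with one column per
#' pairwise comparison ("TvsX", "TvsO", "XvsO" for a trio) and "NA" for
#' undefined scores:
#' \itemize{
#'   \item `ssm_jaccard_by_type.tsv` — mutation-type rows plus an
#'     "All Mutations" row;
#'   \item `sv_chrom_jaccard.tsv` — per-chromosome SV Jaccard rows plus an
#'     "Sc" overall-score row;
#'   \item `sv_category_jaccard.tsv` — genome-wide per-category SV Jaccard;
#'   \item `cn_concordance.tsv` — "genome" row plus per-chromosome
#'     copy-number concordance.
#' }
#' A machine-readable `summary.json` with every computed number (counts,
#' base sums, flags, ploidy QC, config snapshot) is written alongside.
#'
#' @param report A `concordance_report` from [run_patient()].
#' @param out_dir Output directory (created if needed).
#' @return Character vector of written file paths, invisibly.
#' @export
write_report_tables <- function(report, out_dir) {
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE,
                                          showWarnings = FALSE)
  if (!ok || !dir.exists(out_dir))
    abort("cannot create output directory: %s", out_dir)
  written <- character()
  pr <- report$pair_results

  ssm_pairs <- Filter(Negate(is.null), lapply(pr, function(x) {
    if (is.null(x$ssm)) return(NULL)
    rows <- rbind(x$ssm$by_type, x$ssm$overall)
    stats::setNames(rows$jaccard, rows$mutation_type)
  }))
  if (length(ssm_pairs)) {
    types <- sort(setdiff(unique(unlist(lapply(ssm_pairs, names))),
                          "All Mutations"))
    f <- file.path(out_dir, "ssm_jaccard_by_type.tsv")
    write_score_tsv(score_matrix(ssm_pairs,
                                 row_order = c(types, "All Mutations")),
                    f, "mutation_type")
    written <- c(written, f)
  }

  sv_pairs <- Filter(Negate(is.null), lapply(pr, function(x) {
    if (is.null(x$sv)) return(NULL)
    v <- stats::setNames(x$sv$chrom_rows$jaccard, x$sv$chrom_rows$chrom)
    c(v, Sc = x$sv$overall$score)
  }))
  if (length(sv_pairs)) {
    f <- file.path(out_dir, "sv_chrom_jaccard.tsv")
    write_score_tsv(score_matrix(sv_pairs,
                                 row_order = c(default_chromosomes(), "Sc")),
                    f, "chrom")
    written <- c(written, f)
    cat_pairs <- Filter(Negate(is.null), lapply(pr, function(x) {
      if (is.null(x$sv)) return(NULL)
      stats::setNames(x$sv$category_rows$jaccard, x$sv$category_rows$category)
    }))
    f <- file.path(out_dir, "sv_category_jaccard.tsv")
    write_score_tsv(score_matrix(cat_pairs, row_order = sv_categories),
                    f, "category")
    written <- c(written, f)
  }

  cn_pairs <- Filter(Negate(is.null), lapply(pr, function(x) {
    if (is.null(x$cn)) return(NULL)
    stats::setNames(x$cn$table$score, x$cn$table$scope)
  }))
  if (length(cn_pairs)) {
    f <- file.path(out_dir, "cn_concordance.tsv")
    write_score_tsv(score_matrix(cn_pairs,
                                 row_order = c("genome",
                                               default_chromosomes())),
                    f, "scope")
    written <- c(written, f)
  }

  f <- file.path(out_dir, "summary.json")
  jsonlite::write_json(report_to_list(report), f, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  written <- c(written, f)
  invisible(written)
}

# plain-list view of a report for JSON serialization
report_to_list <- function(report) {
  list(
    patient_id = report$patient_id,
    cohort = report$cohort,
    config = report$config,
    pairs = lapply(report$pair_results, function(x) {
      out <- list()
      if (!is.null(x$ssm))
        out$ssm <- list(by_type = x$ssm$by_type, overall = x$ssm$overall)
      if (!is.null(x$sv))
        out$sv <- list(chromosomes = x$sv$chrom_rows,
                       categories = x$sv$category_rows,
                       overall = x$sv$overall)
      if (!is.null(x$cn))
        out$cn <- list(table = x$cn$table, ploidy_qc = x$cn$ploidy_qc)
      out
    })
  )
}
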