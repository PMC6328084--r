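#' Read somatic SNV/indel calls from a VCF file
#'
#' Parses a VCF 4.x file into a [variant_calls()] table. Multi-allelic
#' records are split into one call per ALT allele; each split call inherits
#' the allele depths for its own allele from the AD-style FORMAT field.
#' Positions are kept as-is (VCF is already 1-based).
#'
#' The annotation category is taken from an INFO key (default `MT`); records
#' without it are retained with `mutation_type = "Unannotated"` and a
#' warning. Allele depths come from a FORMAT key (default `AD`, parsed as
#' "ref,alt1,alt2,..."); missing depths become NA.
#'
#' @param path Path to a VCF file.
#' @param sample_id Sample identifier to stamp on every call.
#' @param type_key INFO key holding the mutation-category annotation.
#' @param depth_key FORMAT key holding comma-separated allele depths.
#' @param pass_only If TRUE (default), keep only records whose FILTER is
#'   "PASS" or ".".
#' @return A `variant_calls` data.frame.
#' @export
read_ssm_vcf <- function(path, sample_id, type_key = "MT",
                         depth_key = "AD", pass_only = TRUE) {
  if (!file.exists(path)) abort("VCF file not found: %s", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(fix) || nrow(vcf@fix) == 0)
    return(variant_calls(sample_id = sample_id))
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)

  if (pass_only) {
    keep <- is.na(fix$FILTER) | fix$FILTER %in% c("PASS", ".")
  } else {
    keep <- rep(TRUE, nrow(fix))
  }
  if (!any(keep)) return(variant_calls(sample_id = sample_id))

  mt <- vcfR::extract.info(vcf, element = type_key)
  if (is.null(mt)) mt <- rep(NA_character_, nrow(fix))
  n_missing <- sum(is.na(mt[keep]))
  if (n_missing > 0)
    warn("%d record(s) in %s lack INFO/%s; retained as 'Unannotated'",
         n_missing, basename(path), type_key)
  mt[is.na(mt)] <- "Unannotated"

  ad <- NULL
  if (ncol(vcf@gt %||% matrix(nrow = 0, ncol = 0)) >= 2) {
    ad_mat <- tryCatch(
      vcfR::extract.gt(vcf, element = depth_key),
      error = function(e) NULL
    )
    if (!is.null(ad_mat)) ad <- ad_mat[, 1]
  }
  if (is.null(ad)) ad <- rep(NA_character_, nrow(fix))

  idx <- which(keep)
  out <- vector("list", length(idx))
  for (k in seq_along(idx)) {
    i <- idx[k]
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    depths <- suppressWarnings(
      as.integer(strsplit(ad[i] %||% NA_character_, ",", fixed = TRUE)[[1]])
    )
    rd <- if (length(depths) >= 1) depths[1] else NA_integer_
    alt_d <- vapply(seq_along(alts), function(j) {
      if (length(depths) >= j + 1) depths[j + 1] else NA_integer_
    }, integer(1))
    out[[k]] <- data.frame(
      chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
      ref = fix$REF[i], alt = alts, mutation_type = mt[i],
      ref_depth = rd, alt_depth = alt_d,
      stringsAsFactors = FALSE
    )
  }
  df <- do.call(rbind, out)
  variant_calls(df$chrom, df$pos, df$ref, df$alt, df$mutation_type,
                df$ref_depth, df$alt_depth, sample_id = sample_id)
}

#' Write somatic calls to a minimal VCF file
#'
#' Emits a VCF 4.2 file carrying the mutation category in `INFO/<type_key>`
#' and allele depths in `FORMAT/<depth_key>` for a single sample column.
#' Reading the file back with [read_ssm_vcf()] reproduces the input table.
#'
#' @param calls A `variant_calls` table (one sample).
#' @param path Output path.
#' @param type_key,depth_key Keys to use for annotation and depths.
#' @return `path`, invisibly.
#' @export
write_ssm_vcf <- function(calls, path, type_key = "MT", depth_key = "AD") {
  sample_name <- unique(calls$sample_id)
  sample_name <- sample_name[!is.na(sample_name)]
  if (length(sample_name) != 1) sample_name <- "SAMPLE"
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##INFO=<ID=%s,Number=1,Type=String,Description=\"Mutation category\">",
            type_key),
    sprintf("##FORMAT=<ID=%s,Number=R,Type=Integer,Description=\"Allele depths\">",
            depth_key),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_name), collapse = "\t")
  )
  if (nrow(calls) > 0) {
    ord <- order(match(calls$chrom, sort_chromosomes(calls$chrom)), calls$pos)
    calls <- calls[ord, , drop = FALSE]
    ad <- ifelse(
      is.na(calls$ref_depth) & is.na(calls$alt_depth), ".",
      paste(ifelse(is.na(calls$ref_depth), ".", calls$ref_depth),
            ifelse(is.na(calls$alt_depth), ".", calls$alt_depth), sep = ",")
    )
    body <- paste(calls$chrom, calls$pos, ".", calls$ref, calls$alt, ".",
                  "PASS", paste0(type_key, "=", calls$mutation_type),
                  depth_key, ad, sep = "\t")
  } else {
    body <- character()
  }
  writeLines(c(header, body), path)
  invisible(path)
}
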