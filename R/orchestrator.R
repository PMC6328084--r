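#' Analysis configuration
#'
#' Collects every tunable threshold of the pipeline in one place so a run
#' can log exactly what it used. Defaults are the operative values of the
#' scoring scheme: Jaccard concordance cut 0.6 (inclusive), copy-state
#' tolerance 0.25 on ploidy-rescaled values, clustered-rearrangement flag
#' at >= 5 weighted events in both samples, count-discordance flag at a
#' difference >= 10, exact (0 bp) SV breakpoint matching.
#'
#' @param jaccard_threshold Concordance cut applied to J scores and S^c
#'   positivity.
#' @param cn_tolerance Copy-state agreement tolerance.
#' @param elevated_min,discordant_diff Per-chromosome SV flag thresholds.
#' @param bp_tolerance SV breakpoint match tolerance in bp.
#' @param pass_only Keep only PASS/'.' VCF records.
#' @param type_key,depth_key VCF INFO/FORMAT keys for annotation and
#'   depths.
#' @param cn_denominator "codefined" (literal formula) or "union".
#' @param ploidy_rel_tol Relative tolerance for ploidy QC.
#' @param modules Character subset of c("ssm", "sv", "cnv") to run.
#' @return A named list with class `concord_config`.
#' @export
concord_config <- function(jaccard_threshold = 0.6, cn_tolerance = 0.25,
                           elevated_min = 5, discordant_diff = 10,
                           bp_tolerance = 0, pass_only = TRUE,
                           type_key = "MT", depth_key = "AD",
                           cn_denominator = "codefined",
                           ploidy_rel_tol = 0.1,
                           modules = c("ssm", "sv", "cnv")) {
  structure(
    list(jaccard_threshold = jaccard_threshold,
         cn_tolerance = cn_tolerance, elevated_min = elevated_min,
         discordant_diff = discordant_diff, bp_tolerance = bp_tolerance,
         pass_only = pass_only, type_key = type_key, depth_key = depth_key,
         cn_denominator = cn_denominator, ploidy_rel_tol = ploidy_rel_tol,
         modules = match.arg(modules, several.ok = TRUE)),
    class = "concord_config"
  )
}

pair_label_map <- c(tumour.pdx = "TvsX", tumour.pdo = "TvsO",
                    pdx.pdo = "XvsO")

#' Decompose a patient entry into ordered sample pairs
#'
#' A trio (tumour, PDX, PDO) is analysed as three pairwise comparisons in
#' fixed order: tumour-PDX ("TvsX"), tumour-PDO ("TvsO"), PDX-PDO
#' ("XvsO"). Pairs whose roles are absent are dropped; fewer than two roles
#' is an error.
#'
#' @param entry A manifest entry (see [read_manifest()]).
#' @return A named list (pair label -> character vector of two roles).
#' @export
decompose_trio <- function(entry) {
  roles <- intersect(manifest_roles, names(entry$samples))
  if (length(roles) < 2)
    abort("patient '%s' has fewer than two roles", entry$patient_id %||% "?")
  combos <- list(c("tumour", "pdx"), c("tumour", "pdo"), c("pdx", "pdo"))
  out <- list()
  for (cb in combos) {
    if (all(cb %in% roles))
      out[[pair_label_map[[paste(cb, collapse = ".")]]]] <- cb
  }
  out
}

# score one pair of already-loaded sample data
score_pair <- function(a, b, config) {
  res <- list()
  if ("ssm" %in% config$modules && !is.null(a$ssm) && !is.null(b$ssm)) {
    by_type <- jaccard_by_type(a$ssm, b$ssm)
    overall <- jaccard_all_mutations(a$ssm, b$ssm)
    res$ssm <- list(by_type = by_type, overall = overall)
  }
  if ("sv" %in% config$modules && !is.null(a$sv) && !is.null(b$sv)) {
    chrom_rows <- sv_chromosome_table(
      a$sv, b$sv, tolerance = config$bp_tolerance,
      elevated_min = config$elevated_min,
      discordant_diff = config$discordant_diff
    )
    res$sv <- list(
      chrom_rows = chrom_rows,
      category_rows = category_jaccard(a$sv, b$sv, scope = "genome",
                                       tolerance = config$bp_tolerance),
      overall = overall_concordance(chrom_rows,
                                    threshold = config$jaccard_threshold)
    )
  }
  if ("cnv" %in% config$modules && !is.null(a$cn) && !is.null(b$cn)) {
    blocks <- intersect_segments(
      rescale_by_ploidy(a$cn$segments, a$cn$ploidy),
      rescale_by_ploidy(b$cn$segments, b$cn$ploidy),
      tolerance = config$cn_tolerance
    )
    res$cn <- list(
      table = cn_concordance_table(blocks, tolerance = config$cn_tolerance,
                                   denominator = config$cn_denominator),
      ploidy_qc = ploidy_qc(a$cn$ploidy, b$cn$ploidy,
                            rel_tol = config$ploidy_rel_tol)
    )
  }
  res
}

load_role_data <- function(entry, role, config) {
  files <- entry$files[[role]] %||% list()
  sid <- entry$samples[[role]]
  out <- list()
  if ("ssm" %in% config$modules && !is.null(files$ssm))
    out$ssm <- read_ssm_vcf(files$ssm, sid, type_key = config$type_key,
                            depth_key = config$depth_key,
                            pass_only = config$pass_only)
  if ("sv" %in% config$modules && !is.null(files$sv))
    out$sv <- read_sv_bedpe(files$sv, sid)
  if ("cnv" %in% config$modules && !is.null(files$cn))
    out$cn <- read_cn_segments(files$cn, sid,
                               ploidy_path = files$ploidy %||% NULL)
  out
}

#' Run the full concordance analysis for one patient
#'
#' Reads every input file referenced by the manifest entry (for the
#' modules enabled in `config`), decomposes the patient into ordered
#' pairwise comparisons and scores each pair. The result is deterministic
#' given inputs and configuration.
#'
#' @param entry A manifest entry (see [read_manifest()]).
#' @param config A [concord_config()].
#' @return A `concordance_report`: list with patient_id, cohort,
#'   pair_results (one element per pair label) and a config snapshot.
#' @export
run_patient <- function(entry, config = concord_config()) {
  pairs <- decompose_trio(entry)
  data <- lapply(stats::setNames(nm = names(entry$samples)),
                 function(r) load_role_data(entry, r, config))
  pair_results <- lapply(pairs, function(roles) {
    score_pair(data[[roles[1]]], data[[roles[2]]], config)
  })
  structure(
    list(patient_id = entry$patient_id, cohort = entry$cohort,
         pair_results = pair_results, config = unclass(config)),
    class = "concordance_report"
  )
}

#' Run a whole cohort from a manifest
#'
#' Applies [run_patient()] to every manifest entry. A hard error in one
#' patient is logged to stderr and that patient is skipped; the rest of the
#' cohort still runs.
#'
#' @param manifest A `concord_manifest` (or path to a manifest YAML).
#' @param config A [concord_config()].
#' @return A named list of `concordance_report`s (patients that errored are
#'   absent).
#' @export
run_cohort <- function(manifest, config = concord_config()) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  out <- list()
  for (entry in manifest) {
    rep <- tryCatch(run_patient(entry, config), error = function(e) {
      message(sprintf("patient %s failed: %s", entry$patient_id,
                      conditionMessage(e)))
      NULL
    })
    if (!is.null(rep)) out[[entry$patient_id]] <- rep
  }
  out
}

#' Classify a concordance score
#'
#' Scores at or above the threshold (default 0.6) are "concordant", scores
#' below are "discordant"; an undefined score is NA. On the 0-1 scale, 0
#' means no genomic aberration of the tumour is recapitulated in the model
#' and 1 means all of them are.
#'
#' @param score Numeric score(s) in \[0, 1\], NA allowed.
#' @param threshold Inclusive concordance cut (default 0.6).
#' @return Character vector of "concordant"/"discordant"/NA.
#' @export
classify_score <- function(score, threshold = 0.6) {
  ifelse(is.na(score), NA_character_,
         ifelse(score >= threshold, "concordant", "discordant"))
}
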