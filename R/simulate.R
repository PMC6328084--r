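#' Default mutation-category vocabulary and weights
#'
#' Twelve annotation categories in the style of a functional annotator's
#' output, spanning functional (missense, nonsense, splice-site,
#' frameshift) and non-functional (intronic, UTR, intergenic, lincRNA)
#' classes, with weights loosely reflecting the genome-wide footprint of
#' each class. Weights sum to 1.
#'
#' @return Named numeric vector (category -> sampling weight).
#' @export
default_category_weights <- function() {
  c(Missense_Mutation = 0.18, Nonsense_Mutation = 0.02, Silent = 0.08,
    Splice_Site = 0.01, Intron = 0.30, `3'UTR` = 0.04, `5'UTR` = 0.02,
    `5'Flank` = 0.05, IGR = 0.20, lincRNA = 0.05, RNA = 0.03,
    Frame_Shift_Del = 0.02)
}

#' Default per-chromosome SV simulation profile
#'
#' A handful of chromosomes carrying shared and private events, including
#' one clustered-rearrangement chromosome (chr8) whose six shared events
#' are confined to a 5 Mb window so both samples show an elevated event
#' count and a high per-chromosome Jaccard — the signature of a
#' chromothripsis-like cluster transmitted from tumour to model.
#'
#' @return A data.frame with columns chrom, n_shared, n_tumour_only,
#'   n_model_only, clustered.
#' @export
default_sv_profile <- function() {
  data.frame(
    chrom = c("chr8", "chr3", "chr5", "chr12", "chr17"),
    n_shared = c(6L, 2L, 0L, 1L, 3L),
    n_tumour_only = c(0L, 1L, 2L, 0L, 1L),
    n_model_only = c(0L, 1L, 0L, 1L, 0L),
    clustered = c(TRUE, FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}

#' Build a matched-pair simulation scenario
#'
#' Bundles every knob of the synthetic matched-callset generator. The
#' defaults define the package's reference study conditions: 700 shared /
#' 300 tumour-only / 300 model-only mutations over 12 categories, the SV
#' profile of [default_sv_profile()] plus a few translocations, ~20 Mb
#' copy-number segments with a 0.3 discordant segment fraction, and a
#' whole-genome-doubled model (ploidy factor 2) whose rescaled copy states
#' still agree on concordant segments. The hypermutator flag scales all
#' mutation counts by `hypermutator_factor`, mimicking a mismatch-repair
#' deficient case (many mutations, unchanged SV/CN behaviour).
#'
#' @param seed Integer seed fixing all randomness of the generators.
#' @param genome Named chromosome-length vector (default
#'   [default_genome()]).
#' @param ssm List: n_shared, n_tumour_only, n_model_only,
#'   category_weights.
#' @param sv Data.frame per-chromosome profile (see
#'   [default_sv_profile()]).
#' @param sv_tra List: n_shared, n_tumour_only, n_model_only translocation
#'   counts.
#' @param cn List: segment_mb (mean segment length), tumour_ploidy,
#'   ploidy_factor (model ploidy = tumour ploidy x factor), jitter
#'   (half-width of the rescaled-state jitter on concordant segments; must
#'   be <= tolerance/2), discordant_fraction, tolerance.
#' @param hypermutator Logical; scale mutation counts up.
#' @param hypermutator_factor Multiplier applied when `hypermutator`.
#' @return A list with class `pair_scenario`.
#' @export
pair_scenario <- function(seed = 1L,
                          genome = default_genome(),
                          ssm = list(),
                          sv = default_sv_profile(),
                          sv_tra = list(),
                          cn = list(),
                          hypermutator = FALSE,
                          hypermutator_factor = 10) {
  ssm_def <- list(n_shared = 700L, n_tumour_only = 300L,
                  n_model_only = 300L,
                  category_weights = default_category_weights())
  ssm <- utils::modifyList(ssm_def, ssm)
  tra_def <- list(n_shared = 2L, n_tumour_only = 1L, n_model_only = 1L)
  sv_tra <- utils::modifyList(tra_def, sv_tra)
  cn_def <- list(segment_mb = 20, tumour_ploidy = 1.9, ploidy_factor = 2,
                 jitter = 0.05, discordant_fraction = 0.3,
                 tolerance = 0.25)
  cn <- utils::modifyList(cn_def, cn)
  if (any(unlist(ssm[c("n_shared", "n_tumour_only", "n_model_only")]) < 0))
    abort("SSM counts must be non-negative")
  w <- ssm$category_weights
  if (abs(sum(w) - 1) > 1e-8) abort("category weights must sum to 1")
  if (cn$jitter > cn$tolerance / 2)
    abort("cn jitter %.3g incompatible with agreement guarantee (must be <= tolerance/2 = %.3g)",
          cn$jitter, cn$tolerance / 2)
  if (hypermutator) {
    ssm$n_shared <- as.integer(ssm$n_shared * hypermutator_factor)
    ssm$n_tumour_only <- as.integer(ssm$n_tumour_only * hypermutator_factor)
    ssm$n_model_only <- as.integer(ssm$n_model_only * hypermutator_factor)
  }
  structure(list(seed = as.integer(seed), genome = genome, ssm = ssm,
                 sv = sv, sv_tra = sv_tra, cn = cn,
                 hypermutator = hypermutator),
            class = "pair_scenario")
}

# ---- straight-line truth oracles (generation-time arithmetic, kept
# ---- independent of the scoring modules) ------------------------------

ssm_truth <- function(t_tab, m_tab) {
  # t_tab/m_tab: data.frame(key, type)
  jac <- function(a, b) {
    s <- length(intersect(a, b))
    d <- length(a) + length(b) - s
    if (d > 0) s / d else NA_real_
  }
  types <- sort(unique(c(t_tab$type, m_tab$type)))
  by_type <- data.frame(
    mutation_type = types,
    jaccard = vapply(types, function(ty) {
      jac(unique(t_tab$key[t_tab$type == ty]),
          unique(m_tab$key[m_tab$type == ty]))
    }, numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  list(by_type = by_type,
       overall = jac(unique(t_tab$key), unique(m_tab$key)))
}

sv_truth <- function(t_ev, m_ev, threshold = 0.6) {
  # identity strings; exact-breakpoint sharing known from equality
  idstr <- function(e) paste(e$chrom_a, e$pos_a, e$chrom_b, e$pos_b,
                             e$category, sep = "|")
  t_id <- unique(idstr(t_ev)); m_id <- unique(idstr(m_ev))
  shared_id <- intersect(t_id, m_id)
  parse_contrib <- function(ids) {
    # per-chromosome base sums and weighted counts from identity strings
    sums <- list(); counts <- list()
    for (id in ids) {
      f <- strsplit(id, "|", fixed = TRUE)[[1]]
      ca <- f[1]; pa <- as.numeric(f[2]); cb <- f[3]; pb <- as.numeric(f[4])
      if (f[5] == "TRA") {
        for (ch in c(ca, cb)) {
          sums[[ch]] <- (sums[[ch]] %||% 0) + 1
          counts[[ch]] <- (counts[[ch]] %||% 0) + 0.5
        }
      } else {
        sums[[ca]] <- (sums[[ca]] %||% 0) + (pb - pa)
        counts[[ca]] <- (counts[[ca]] %||% 0) + 1
      }
    }
    list(sums = sums, counts = counts)
  }
  tc <- parse_contrib(t_id); mc <- parse_contrib(m_id)
  sc <- parse_contrib(shared_id)
  chroms <- sort_chromosomes(unique(c(names(tc$sums), names(mc$sums))))
  g <- function(l, ch) l[[ch]] %||% 0
  jv <- vapply(chroms, function(ch) {
    tt <- g(tc$sums, ch); mm <- g(mc$sums, ch); ss <- g(sc$sums, ch)
    den <- tt + mm - ss
    if (den > 0) ss / den else NA_real_
  }, numeric(1))
  defined <- !is.na(jv)
  p <- sum(defined & jv >= threshold); n <- sum(defined & jv < threshold)
  list(
    chrom_jaccard = stats::setNames(jv, chroms),
    t_counts = vapply(chroms, function(ch) g(tc$counts, ch), numeric(1)),
    m_counts = vapply(chroms, function(ch) g(mc$counts, ch), numeric(1)),
    sc = if (p + n > 0) p / (p + n) else NA_real_
  )
}

cn_truth <- function(seg, tolerance) {
  # seg: data.frame(chrom, len, res_a, res_b) with rescaled states
  agree <- abs(seg$res_a - seg$res_b) <= tolerance
  per_chrom <- vapply(
    sort_chromosomes(unique(seg$chrom)),
    function(ch) {
      i <- seg$chrom == ch
      sum(seg$len[i & agree]) / sum(seg$len[i])
    }, numeric(1))
  list(genome = sum(seg$len[agree]) / sum(seg$len),
       per_chromosome = per_chrom)
}

# ---- generators -------------------------------------------------------

# sample n distinct variant keys on the genome, avoiding `avoid` keys
sample_variant_sites <- function(n, genome, avoid = character()) {
  if (n == 0)
    return(data.frame(chrom = character(), pos = integer(),
                      stringsAsFactors = FALSE))
  if (sum(as.numeric(genome)) < 10 * n)
    abort("genome too small to host %d distinct variant sites", n)
  chrom <- character(0); pos <- integer(0)
  while (length(chrom) < n) {
    k <- n - length(chrom)
    ch <- sample(names(genome), 2 * k + 10, replace = TRUE,
                 prob = as.numeric(genome))
    pp <- vapply(ch, function(c1) sample.int(genome[[c1]], 1L), integer(1))
    key <- paste(ch, pp)
    keep <- !duplicated(key) & !key %in% c(avoid, paste(chrom, pos))
    chrom <- c(chrom, ch[keep]); pos <- c(pos, pp[keep])
  }
  data.frame(chrom = chrom[seq_len(n)], pos = pos[seq_len(n)],
             row.names = NULL, stringsAsFactors = FALSE)
}

bases <- c("A", "C", "G", "T")

make_calls <- function(sites, types, sample_id) {
  n <- nrow(sites)
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))
  depth <- stats::rpois(n, 60)
  alt_d <- stats::rbinom(n, depth, 0.4)
  variant_calls(sites$chrom, sites$pos, ref, alt, types,
                ref_depth = depth - alt_d, alt_depth = alt_d,
                sample_id = sample_id)
}

#' Simulate a matched tumour/model mutation pair with known truth
#'
#' Draws exactly `n_shared` variants present identically in both samples,
#' `n_tumour_only` private to the tumour and `n_model_only` private to the
#' model, all at distinct genomic sites, with categories drawn from the
#' scenario's weight table. Shared variants carry the same category in both
#' samples (read depths are drawn independently — they are not part of
#' variant identity). The truth record holds the exact per-category and
#' overall Jaccard indices implied by the realized category assignment,
#' computed by plain set arithmetic at generation time.
#'
#' @param scenario A [pair_scenario()].
#' @param seed Seed (defaults to the scenario's).
#' @param sample_ids Length-2 character: tumour and model sample ids.
#' @return A list: `tumour`, `model` (`variant_calls`) and `truth`.
#' @export
simulate_pair_ssm <- function(scenario, seed = scenario$seed,
                              sample_ids = c("SIM_T", "SIM_X")) {
  set.seed(seed)
  s <- scenario$ssm
  n_tot <- s$n_shared + s$n_tumour_only + s$n_model_only
  sites <- sample_variant_sites(n_tot, scenario$genome)
  types <- sample(names(s$category_weights), n_tot, replace = TRUE,
                  prob = s$category_weights)
  i_sh <- seq_len(s$n_shared)
  i_t <- seq_len(s$n_tumour_only) + s$n_shared
  i_m <- seq_len(s$n_model_only) + s$n_shared + s$n_tumour_only
  tumour <- make_calls(sites[c(i_sh, i_t), , drop = FALSE],
                       types[c(i_sh, i_t)], sample_ids[1])
  model <- make_calls(sites[c(i_sh, i_m), , drop = FALSE],
                      types[c(i_sh, i_m)], sample_ids[2])
  # identity keys differ between samples unless ref/alt agree: force the
  # shared block to carry the tumour's alleles in the model too
  model$ref[seq_len(s$n_shared)] <- tumour$ref[seq_len(s$n_shared)]
  model$alt[seq_len(s$n_shared)] <- tumour$alt[seq_len(s$n_shared)]
  key <- function(calls) paste(calls$chrom, calls$pos, calls$ref, calls$alt)
  truth <- ssm_truth(
    data.frame(key = key(tumour), type = tumour$mutation_type),
    data.frame(key = key(model), type = model$mutation_type)
  )
  list(tumour = tumour, model = model, truth = truth)
}

# generate intra-chromosomal events on one chromosome
gen_intra_events <- function(n, chrom, len, clustered, sample_id) {
  if (n == 0) return(sv_events(sample_id = sample_id))
  if (clustered) {
    win <- 5e6
    w0 <- sample.int(max(1L, as.integer(len - win)), 1L)
    lo <- w0; hi <- w0 + win
  } else {
    lo <- 1L; hi <- len
  }
  size <- sample.int(9.5e5, n) + 5e4L  # 50 kb - 1 Mb
  pos_a <- vapply(size, function(sz) {
    lo + sample.int(as.integer(hi - sz - lo + 1L), 1L) - 1L
  }, integer(1))
  cat <- sample(c("DEL", "DUP", "INV"), n, replace = TRUE)
  sv_events(chrom, pos_a, chrom, pos_a + size, cat, sample_id = sample_id)
}

gen_tra_events <- function(n, genome, sample_id) {
  if (n == 0) return(sv_events(sample_id = sample_id))
  ch <- t(vapply(seq_len(n), function(i) sample(names(genome), 2L),
                 character(2)))
  pa <- vapply(ch[, 1], function(c1) sample.int(genome[[c1]], 1L),
               integer(1))
  pb <- vapply(ch[, 2], function(c1) sample.int(genome[[c1]], 1L),
               integer(1))
  sv_events(ch[, 1], pa, ch[, 2], pb, "TRA", sample_id = sample_id)
}

#' Simulate a matched structural-variant pair with known truth
#'
#' Follows the scenario's per-chromosome profile: shared events have
#' identical breakpoints in both samples; chromosomes flagged `clustered`
#' receive their events inside one 5 Mb window (so both samples show an
#' elevated weighted count and, with all events shared, a per-chromosome
#' Jaccard of 1). Translocations are added between random chromosome
#' pairs. The truth record holds per-chromosome size-weighted Jaccard
#' indices, weighted counts and the overall S^c, computed from the realized
#' breakpoints by straight-line arithmetic.
#'
#' @inheritParams simulate_pair_ssm
#' @return A list: `tumour`, `model` (`sv_events`) and `truth`.
#' @export
simulate_pair_sv <- function(scenario, seed = scenario$seed,
                             sample_ids = c("SIM_T", "SIM_X")) {
  set.seed(seed + 1L)
  prof <- scenario$sv
  t_parts <- list(); m_parts <- list()
  for (i in seq_len(nrow(prof))) {
    ch <- prof$chrom[i]
    len <- scenario$genome[[ch]]
    shared <- gen_intra_events(prof$n_shared[i], ch, len,
                               prof$clustered[i], sample_ids[1])
    t_only <- gen_intra_events(prof$n_tumour_only[i], ch, len,
                               prof$clustered[i], sample_ids[1])
    m_only <- gen_intra_events(prof$n_model_only[i], ch, len,
                               prof$clustered[i], sample_ids[2])
    shared_m <- shared
    shared_m$sample_id <- rep(sample_ids[2], nrow(shared_m))
    t_parts <- c(t_parts, list(shared, t_only))
    m_parts <- c(m_parts, list(shared_m, m_only))
  }
  tra_sh <- gen_tra_events(scenario$sv_tra$n_shared, scenario$genome,
                           sample_ids[1])
  tra_t <- gen_tra_events(scenario$sv_tra$n_tumour_only, scenario$genome,
                          sample_ids[1])
  tra_m <- gen_tra_events(scenario$sv_tra$n_model_only, scenario$genome,
                          sample_ids[2])
  tra_sh_m <- tra_sh
  tra_sh_m$sample_id <- rep(sample_ids[2], nrow(tra_sh_m))
  tumour <- do.call(rbind, c(t_parts, list(tra_sh, tra_t)))
  model <- do.call(rbind, c(m_parts, list(tra_sh_m, tra_m)))
  class(tumour) <- class(model) <- c("sv_events", "data.frame")
  list(tumour = tumour, model = model, truth = sv_truth(tumour, model))
}

#' Simulate a matched copy-number pair with known truth
#'
#' Cuts every chromosome into segments of roughly `segment_mb` megabases
#' shared by both samples. The tumour's rescaled copy state per segment is
#' drawn from a discrete set around 1; its `imean` is that state times the
#' tumour ploidy. The model's ploidy is `tumour_ploidy * ploidy_factor`;
#' on concordant segments its rescaled state equals the tumour's plus a
#' jitter bounded by `tolerance / 2` (so rescaled agreement is guaranteed),
#' and on the designated discordant fraction it is offset by twice the
#' tolerance (so disagreement is guaranteed). The truth record stores the
#' exact genome-wide and per-chromosome agreement fractions from the
#' realized segment lengths.
#'
#' @inheritParams simulate_pair_ssm
#' @return A list: `tumour` and `model` (each a list of `segments` and
#'   `ploidy`) and `truth`.
#' @export
simulate_pair_cn <- function(scenario, seed = scenario$seed,
                             sample_ids = c("SIM_T", "SIM_X")) {
  set.seed(seed + 2L)
  cn <- scenario$cn
  genome <- scenario$genome
  segs <- list()
  for (ch in names(genome)) {
    len <- genome[[ch]]
    n_seg <- max(1L, round(len / (cn$segment_mb * 1e6)))
    cuts <- sort(sample.int(len - 1L, n_seg - 1L))
    start <- c(0, cuts); end <- c(cuts, len)
    segs[[ch]] <- data.frame(chrom = ch, start = start, end = end,
                             stringsAsFactors = FALSE)
  }
  seg <- do.call(rbind, segs)
  rownames(seg) <- NULL
  n <- nrow(seg)
  res_t <- sample(c(0.5, 0.75, 1, 1.25, 1.5, 2), n, replace = TRUE,
                  prob = c(0.1, 0.15, 0.4, 0.15, 0.1, 0.1))
  discordant <- stats::runif(n) < cn$discordant_fraction
  jit <- stats::runif(n, -cn$jitter, cn$jitter)
  offset <- ifelse(res_t < 1.5, 2 * cn$tolerance, -2 * cn$tolerance)
  res_m <- ifelse(discordant, res_t + offset, res_t + jit)
  p_t <- cn$tumour_ploidy
  p_m <- cn$tumour_ploidy * cn$ploidy_factor
  truth <- cn_truth(
    data.frame(chrom = seg$chrom, len = seg$end - seg$start,
               res_a = res_t, res_b = res_m),
    tolerance = cn$tolerance
  )
  list(
    tumour = list(
      segments = cn_segments(seg$chrom, seg$start, seg$end, res_t * p_t,
                             sample_id = sample_ids[1]),
      ploidy = sample_ploidy(sample_ids[1], p_t)
    ),
    model = list(
      segments = cn_segments(seg$chrom, seg$start, seg$end, res_m * p_m,
                             sample_id = sample_ids[2]),
      ploidy = sample_ploidy(sample_ids[2], p_m)
    ),
    truth = truth
  )
}

#' Simulate a complete tumour/PDX/PDO trio with known truth
#'
#' Generates the tumour-PDX pair from the scenario, then derives the
#' organoid from the *PDX* (not the tumour) by perturbation — dropping a
#' fraction of the PDX's mutations and SV events, adding new private ones,
#' and re-jittering / re-offsetting the PDX's copy-number profile — which
#' reproduces the expected ordering that PDX-PDO concordance exceeds
#' tumour-PDO concordance. Truth records for all three pairwise
#' comparisons (TvsX, TvsO, XvsO) are computed from the realized call sets
#' by the same straight-line arithmetic as the pair generators.
#'
#' When `out_dir` is given, writes per-sample VCF / BEDPE / segment files,
#' a ploidy table, a manifest usable by [run_cohort()], and a
#' `truth.json`.
#'
#' @param scenario A [pair_scenario()].
#' @param seed Seed (defaults to the scenario's).
#' @param patient_id Patient identifier used for sample ids and the
#'   manifest.
#' @param perturb List of perturbation rates for deriving the organoid
#'   from the PDX: ssm_drop, ssm_add, sv_drop, sv_add, cn_discordant.
#' @param out_dir Optional output directory.
#' @return A list: `samples` (tumour/pdx/pdo data bundles), `truth` (per
#'   pair label), `manifest_entry`, and `paths` when files were written.
#' @export
simulate_trio <- function(scenario = pair_scenario(),
                          seed = scenario$seed,
                          patient_id = "SIM_0001",
                          perturb = list(),
                          out_dir = NULL) {
  perturb <- utils::modifyList(
    list(ssm_drop = 0.1, ssm_add = 0.1, sv_drop = 0.15, sv_add = 0.1,
         cn_discordant = 0.1),
    perturb
  )
  ids <- paste0(patient_id, c("_T", "_X", "_O"))

  ssm <- simulate_pair_ssm(scenario, seed = seed, sample_ids = ids[1:2])
  sv <- simulate_pair_sv(scenario, seed = seed, sample_ids = ids[1:2])
  cnp <- simulate_pair_cn(scenario, seed = seed, sample_ids = ids[1:2])

  set.seed(seed + 3L)
  # --- organoid mutations: perturb the PDX call set
  x_calls <- ssm$model
  keep <- stats::runif(nrow(x_calls)) >= perturb$ssm_drop
  o_calls <- x_calls[keep, , drop = FALSE]
  n_add <- round(perturb$ssm_add * nrow(x_calls))
  key <- function(calls) paste(calls$chrom, calls$pos)
  add_sites <- sample_variant_sites(
    n_add, scenario$genome,
    avoid = unique(c(key(ssm$tumour), key(x_calls)))
  )
  add_types <- sample(names(scenario$ssm$category_weights), n_add,
                      replace = TRUE,
                      prob = scenario$ssm$category_weights)
  o_calls <- rbind(o_calls, make_calls(add_sites, add_types, ids[3]))
  o_calls$sample_id <- rep(ids[3], nrow(o_calls))
  class(o_calls) <- c("variant_calls", "data.frame")

  # --- organoid SVs: perturb the PDX events
  x_ev <- sv$model
  keep <- stats::runif(nrow(x_ev)) >= perturb$sv_drop
  o_ev <- x_ev[keep, , drop = FALSE]
  n_add <- round(perturb$sv_add * nrow(x_ev))
  if (n_add > 0) {
    add_chrom <- sample(names(scenario$genome), n_add, replace = TRUE)
    adds <- do.call(rbind, lapply(add_chrom, function(ch) {
      gen_intra_events(1L, ch, scenario$genome[[ch]], FALSE, ids[3])
    }))
    o_ev <- rbind(o_ev, adds)
  }
  o_ev$sample_id <- rep(ids[3], nrow(o_ev))
  class(o_ev) <- c("sv_events", "data.frame")

  # --- organoid copy number: re-perturb the PDX profile (same ploidy)
  x_seg <- cnp$model$segments
  p_x <- cnp$model$ploidy$ploidy
  res_x <- x_seg$imean / p_x
  n <- nrow(x_seg)
  tol <- scenario$cn$tolerance
  disc <- stats::runif(n) < perturb$cn_discordant
  jit <- stats::runif(n, -scenario$cn$jitter, scenario$cn$jitter)
  offset <- ifelse(res_x < 1.5, 2 * tol, -2 * tol)
  res_o <- ifelse(disc, res_x + offset, res_x + jit)
  o_cn <- list(
    segments = cn_segments(x_seg$chrom, x_seg$start, x_seg$end,
                           res_o * p_x, sample_id = ids[3]),
    ploidy = sample_ploidy(ids[3], p_x)
  )

  # --- truth for all three pairwise comparisons
  ssm_tab <- function(calls) data.frame(
    key = paste(calls$chrom, calls$pos, calls$ref, calls$alt),
    type = calls$mutation_type, stringsAsFactors = FALSE)
  res_t <- cnp$tumour$segments$imean / cnp$tumour$ploidy$ploidy
  seg_frame <- function(a, b) data.frame(
    chrom = x_seg$chrom, len = x_seg$end - x_seg$start,
    res_a = a, res_b = b, stringsAsFactors = FALSE)
  truth <- list(
    TvsX = list(ssm = ssm$truth, sv = sv$truth, cn = cnp$truth),
    TvsO = list(ssm = ssm_truth(ssm_tab(ssm$tumour), ssm_tab(o_calls)),
                sv = sv_truth(sv$tumour, o_ev),
                cn = cn_truth(seg_frame(res_t, res_o), tol)),
    XvsO = list(ssm = ssm_truth(ssm_tab(x_calls), ssm_tab(o_calls)),
                sv = sv_truth(x_ev, o_ev),
                cn = cn_truth(seg_frame(res_x, res_o), tol))
  )

  samples <- list(
    tumour = list(ssm = ssm$tumour, sv = sv$tumour, cn = cnp$tumour),
    pdx = list(ssm = x_calls, sv = x_ev, cn = cnp$model),
    pdo = list(ssm = o_calls, sv = o_ev, cn = o_cn)
  )

  paths <- NULL
  entry <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- list()
    for (role in names(samples)) {
      sid <- samples[[role]]$ssm$sample_id[1]
      f <- list(
        ssm = file.path(out_dir, paste0(sid, ".vcf")),
        sv = file.path(out_dir, paste0(sid, ".bedpe")),
        cn = file.path(out_dir, paste0(sid, ".seg"))
      )
      write_ssm_vcf(samples[[role]]$ssm, f$ssm)
      write_sv_bedpe(samples[[role]]$sv, f$sv)
      write_cn_segments(samples[[role]]$cn$segments,
                        samples[[role]]$cn$ploidy, f$cn)
      files[[role]] <- f
    }
    ploidy_path <- file.path(out_dir, "ploidy.tsv")
    write_ploidy_table(lapply(samples, function(s) s$cn$ploidy),
                       ploidy_path)
    entry <- structure(
      list(patient_id = patient_id, cohort = "primary",
           samples = list(tumour = ids[1], pdx = ids[2], pdo = ids[3]),
           files = files),
      class = "manifest_entry"
    )
    manifest_path <- file.path(out_dir, "manifest.yaml")
    write_manifest(list(entry), manifest_path)
    truth_path <- file.path(out_dir, "truth.json")
    jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
    paths <- list(manifest = manifest_path, truth = truth_path,
                  files = files, ploidy = ploidy_path)
  } else {
    entry <- structure(
      list(patient_id = patient_id, cohort = "primary",
           samples = list(tumour = ids[1], pdx = ids[2], pdo = ids[3]),
           files = list()),
      class = "manifest_entry"
    )
  }

  list(samples = samples, truth = truth, manifest_entry = entry,
       paths = paths)
}
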