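#' Genomic size of structural-variant events
#'
#' Intra-chromosomal events (DEL, DUP, INV) span `pos_b - pos_a` bases
#' between their breakpoints; translocations have no interval, so their
#' affected-base total is fixed at 1.
#'
#' @param events An `sv_events` table.
#' @return Numeric vector of event sizes.
#' @export
sv_event_size <- function(events) {
  if (nrow(events) == 0) return(numeric())
  ifelse(events$category == "TRA", 1, events$pos_b - events$pos_a)
}

# collapse duplicate identical events within one sample (set semantics)
dedupe_sv_events <- function(events) {
  if (nrow(events) == 0) return(events)
  key <- paste(events$chrom_a, events$pos_a, events$chrom_b, events$pos_b,
               events$category, sep = "\r")
  events[!duplicated(key), , drop = FALSE]
}

#' Weighted SV event counts per chromosome
#'
#' Each intra-chromosomal event (DEL, DUP, INV) contributes 1 to its
#' chromosome; each translocation contributes 0.5 to each of the two
#' chromosomes it joins. The weighted counts therefore sum to the number of
#' intra-chromosomal events plus the number of translocations.
#'
#' @param events An `sv_events` table (one sample).
#' @param chromosomes Optional chromosome names to force into the result
#'   with count 0.
#' @return Named numeric vector of weighted counts.
#' @export
count_events_per_chromosome <- function(events, chromosomes = NULL) {
  counts <- stats::setNames(rep(0, length(chromosomes)), chromosomes)
  if (nrow(events) > 0) {
    intra <- events$category != "TRA"
    chrom <- c(events$chrom_a[intra], events$chrom_a[!intra],
               events$chrom_b[!intra])
    weight <- c(rep(1, sum(intra)), rep(0.5, 2 * sum(!intra)))
    agg <- tapply(weight, chrom, sum)
    for (ch in names(agg)) {
      prev <- if (ch %in% names(counts)) counts[[ch]] else 0
      counts[ch] <- prev + agg[[ch]]
    }
  }
  counts[sort_chromosomes(names(counts))]
}

#' Flag chromosomes with clustered or discordant SV load
#'
#' A chromosome is flagged *elevated* when both samples carry at least
#' `elevated_min` weighted events on it (clustered rearrangements in tumour
#' and model alike, suggestive of chromothripsis), and *discordant* when the
#' two samples' weighted counts differ by at least `discordant_diff`.
#'
#' @param t_counts,m_counts Named weighted counts from
#'   [count_events_per_chromosome()] for the two samples.
#' @param elevated_min Minimum events in both samples (default 5).
#' @param discordant_diff Minimum count difference (default 10).
#' @return A data.frame with columns chrom, t_events, m_events, elevated,
#'   discordant_count.
#' @export
flag_chromosomes <- function(t_counts, m_counts, elevated_min = 5,
                             discordant_diff = 10) {
  chroms <- sort_chromosomes(unique(c(names(t_counts), names(m_counts))))
  t <- ifelse(is.na(t_counts[chroms]), 0, t_counts[chroms])
  m <- ifelse(is.na(m_counts[chroms]), 0, m_counts[chroms])
  data.frame(
    chrom = chroms, t_events = as.numeric(t), m_events = as.numeric(m),
    elevated = t >= elevated_min & m >= elevated_min,
    discordant_count = abs(t - m) >= discordant_diff,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Match identical SV events between two samples
#'
#' An event in one sample matches an event in the other iff both
#' breakpoints' chromosomes and positions and the category agree, with the
#' positional equality relaxed by `tolerance` base pairs (default 0:
#' exact). Each event matches at most once; candidates are consumed
#' greedily in breakpoint-position order. Duplicate identical events within
#' a sample are collapsed first.
#'
#' @param t_events,m_events `sv_events` tables for the two samples.
#' @param tolerance Maximum per-breakpoint offset in bp for a match.
#' @return A list: `t_events` and `m_events` (deduplicated inputs),
#'   `t_matched` / `m_matched` (logical vectors), and `pairs` (data.frame of
#'   matched row indices `t_idx`, `m_idx`).
#' @export
match_sv_events <- function(t_events, m_events, tolerance = 0) {
  t_events <- dedupe_sv_events(t_events)
  m_events <- dedupe_sv_events(m_events)
  nt <- nrow(t_events); nm <- nrow(m_events)
  t_matched <- rep(FALSE, nt); m_matched <- rep(FALSE, nm)
  pairs <- list()
  if (nt > 0 && nm > 0) {
    t_ord <- order(t_events$chrom_a, t_events$pos_a, t_events$chrom_b,
                   t_events$pos_b)
    m_ord <- order(m_events$chrom_a, m_events$pos_a, m_events$chrom_b,
                   m_events$pos_b)
    for (i in t_ord) {
      for (j in m_ord) {
        if (m_matched[j]) next
        if (t_events$category[i] != m_events$category[j]) next
        if (t_events$chrom_a[i] != m_events$chrom_a[j]) next
        if (t_events$chrom_b[i] != m_events$chrom_b[j]) next
        if (abs(t_events$pos_a[i] - m_events$pos_a[j]) > tolerance) next
        if (abs(t_events$pos_b[i] - m_events$pos_b[j]) > tolerance) next
        t_matched[i] <- TRUE
        m_matched[j] <- TRUE
        pairs[[length(pairs) + 1L]] <- c(t_idx = i, m_idx = j)
        break
      }
    }
  }
  pairs <- if (length(pairs)) as.data.frame(do.call(rbind, pairs)) else
    data.frame(t_idx = integer(), m_idx = integer())
  list(t_events = t_events, m_events = m_events,
       t_matched = t_matched, m_matched = m_matched, pairs = pairs)
}

# per-chromosome size contribution of a set of events: intra events add
# their size to their chromosome; TRA events add 1 to each involved
# chromosome (size rule preserved per chromosome)
chrom_size_sums <- function(events) {
  if (nrow(events) == 0) return(stats::setNames(numeric(), character()))
  sizes <- sv_event_size(events)
  intra <- events$category != "TRA"
  contrib <- c(stats::setNames(sizes[intra], events$chrom_a[intra]),
               stats::setNames(rep(1, sum(!intra)), events$chrom_a[!intra]),
               stats::setNames(rep(1, sum(!intra)), events$chrom_b[!intra]))
  out <- tapply(contrib, names(contrib), sum)
  stats::setNames(as.numeric(out), names(out))
}

#' Per-chromosome size-weighted SV Jaccard table
#'
#' For each chromosome V: T_V and P_V are the summed genomic sizes of the
#' tumour's and the model's SV events on V (translocations contribute 1 to
#' each involved chromosome); C_V is the summed size of events identical in
#' both samples (same breakpoints and category, see [match_sv_events()]).
#' J_V = C_V / (T_V + P_V - C_V), undefined (NA) on chromosomes with no
#' event in either sample. Weighted event counts and the elevated /
#' discordant-count flags are carried along.
#'
#' @param t_events,m_events `sv_events` tables for the two samples.
#' @param tolerance Breakpoint match tolerance in bp (default 0).
#' @param elevated_min,discordant_diff Flag thresholds, see
#'   [flag_chromosomes()].
#' @param chromosomes Chromosome universe to report (default: autosomes +
#'   chrX + chrY, plus any other chromosome present in the data).
#' @return A data.frame with one row per chromosome: chrom, t_bases,
#'   m_bases, shared_bases, jaccard, t_events, m_events, elevated,
#'   discordant_count.
#' @export
sv_chromosome_table <- function(t_events, m_events, tolerance = 0,
                                elevated_min = 5, discordant_diff = 10,
                                chromosomes = default_chromosomes()) {
  mt <- match_sv_events(t_events, m_events, tolerance = tolerance)
  t_ev <- mt$t_events; m_ev <- mt$m_events
  shared_ev <- t_ev[mt$pairs$t_idx, , drop = FALSE]

  present <- unique(c(t_ev$chrom_a, t_ev$chrom_b, m_ev$chrom_a,
                      m_ev$chrom_b))
  chroms <- sort_chromosomes(unique(c(chromosomes, present)))

  t_sum <- chrom_size_sums(t_ev)
  m_sum <- chrom_size_sums(m_ev)
  c_sum <- chrom_size_sums(shared_ev)
  pick <- function(v, ch) if (ch %in% names(v)) v[[ch]] else 0

  flags <- flag_chromosomes(
    count_events_per_chromosome(t_ev, chromosomes = chroms),
    count_events_per_chromosome(m_ev, chromosomes = chroms),
    elevated_min = elevated_min, discordant_diff = discordant_diff
  )

  rows <- lapply(chroms, function(ch) {
    tb <- pick(t_sum, ch); mb <- pick(m_sum, ch); cb <- pick(c_sum, ch)
    denom <- tb + mb - cb
    data.frame(chrom = ch, t_bases = tb, m_bases = mb, shared_bases = cb,
               jaccard = if (denom > 0) cb / denom else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  fl <- flags[match(out$chrom, flags$chrom), , drop = FALSE]
  out <- cbind(out, fl[, c("t_events", "m_events", "elevated",
                           "discordant_count"), drop = FALSE])
  rownames(out) <- NULL
  out
}

#' Size-weighted SV Jaccard for one chromosome
#'
#' Single-chromosome view of [sv_chromosome_table()].
#'
#' @inheritParams sv_chromosome_table
#' @param chrom Chromosome name.
#' @return A one-row data.frame.
#' @export
chromosome_jaccard <- function(t_events, m_events, chrom, tolerance = 0,
                               elevated_min = 5, discordant_diff = 10) {
  tab <- sv_chromosome_table(t_events, m_events, tolerance = tolerance,
                             elevated_min = elevated_min,
                             discordant_diff = discordant_diff,
                             chromosomes = chrom)
  tab[tab$chrom == chrom, , drop = FALSE]
}

#' Overall SV concordance score across chromosomes
#'
#' S^c = P / (P + N), where P is the number of chromosomes with a defined
#' per-chromosome Jaccard J_V >= `threshold` and N the number with a
#' defined J_V below it. Chromosomes harbouring no SV event in either
#' sample (undefined J_V) enter neither P nor N; with no qualifying
#' chromosome the score is NA.
#'
#' @param chrom_rows Output of [sv_chromosome_table()].
#' @param threshold Positive-chromosome cut on J_V (default 0.6,
#'   inclusive).
#' @return A list with elements positives, negatives, score.
#' @export
overall_concordance <- function(chrom_rows, threshold = 0.6) {
  j <- chrom_rows$jaccard
  defined <- !is.na(j)
  p <- sum(defined & j >= threshold)
  n <- sum(defined & j < threshold)
  list(positives = p, negatives = n,
       score = if (p + n > 0) p / (p + n) else NA_real_)
}

#' Size-weighted SV Jaccard per event category
#'
#' For each category K in DEL, DUP, INV, TRA: T_K, P_K and C_K are the
#' summed genomic sizes of the tumour's, the model's, and the shared events
#' of that category, and J_K = C_K / (T_K + P_K - C_K). Scope is either
#' "genome" (all chromosomes) or one chromosome name, in which case sums are
#' restricted to events touching that chromosome (a translocation
#' contributes 1 if either breakpoint lies on it). Categories with no event
#' in either sample within the scope are omitted.
#'
#' @inheritParams sv_chromosome_table
#' @param scope "genome" or a chromosome name.
#' @return A data.frame with columns category, scope, t_bases, m_bases,
#'   shared_bases, jaccard.
#' @export
category_jaccard <- function(t_events, m_events, scope = "genome",
                             tolerance = 0) {
  mt <- match_sv_events(t_events, m_events, tolerance = tolerance)
  t_ev <- mt$t_events; m_ev <- mt$m_events
  shared_ev <- t_ev[mt$pairs$t_idx, , drop = FALSE]

  scoped_sum <- function(ev, cat) {
    ev <- ev[ev$category == cat, , drop = FALSE]
    if (nrow(ev) == 0) return(0)
    if (identical(scope, "genome")) return(sum(sv_event_size(ev)))
    # chromosome scope: same attribution rule as chrom_size_sums
    s <- chrom_size_sums(ev)
    if (scope %in% names(s)) s[[scope]] else 0
  }
  rows <- lapply(sv_categories, function(cat) {
    tb <- scoped_sum(t_ev, cat)
    mb <- scoped_sum(m_ev, cat)
    cb <- scoped_sum(shared_ev, cat)
    denom <- tb + mb - cb
    if (denom <= 0 && tb + mb == 0) return(NULL)  # category absent in scope
    data.frame(category = cat, scope = scope, t_bases = tb, m_bases = mb,
               shared_bases = cb,
               jaccard = if (denom > 0) cb / denom else NA_real_,
               stringsAsFactors = FALSE)
  })
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0)
    return(data.frame(category = character(), scope = character(),
                      t_bases = numeric(), m_bases = numeric(),
                      shared_bases = numeric(), jaccard = numeric(),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
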