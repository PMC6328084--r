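# Brute-force oracles, deliberately written with plain loops and no calls
# into the package's scoring code, plus small random-instance generators.

oracle_set_jaccard <- function(a, b) {
  a <- unique(a)
  b <- unique(b)
  inter <- 0L
  for (x in a) if (any(b == x)) inter <- inter + 1L
  uni <- length(a) + length(b) - inter
  if (uni == 0) NA_real_ else inter / uni
}

# size contribution of one event to one chromosome (TRA: 1 per touched side)
oracle_event_size_on <- function(ev, i, chrom) {
  if (ev$category[i] == "TRA") {
    s <- 0
    if (ev$chrom_a[i] == chrom) s <- s + 1
    if (ev$chrom_b[i] == chrom) s <- s + 1
    s
  } else if (ev$chrom_a[i] == chrom) {
    ev$pos_b[i] - ev$pos_a[i]
  } else 0
}

oracle_sv_id <- function(ev) {
  paste(ev$chrom_a, ev$pos_a, ev$chrom_b, ev$pos_b, ev$category)
}

oracle_sv_dedupe <- function(ev) ev[!duplicated(oracle_sv_id(ev)), , drop = FALSE]

# size-weighted Jaccard on one chromosome (exact breakpoint matching)
oracle_sv_chrom_jaccard <- function(t_ev, m_ev, chrom) {
  t_ev <- oracle_sv_dedupe(t_ev)
  m_ev <- oracle_sv_dedupe(m_ev)
  shared <- t_ev[oracle_sv_id(t_ev) %in% oracle_sv_id(m_ev), , drop = FALSE]
  tot <- function(ev) {
    s <- 0
    for (i in seq_len(nrow(ev))) s <- s + oracle_event_size_on(ev, i, chrom)
    s
  }
  tt <- tot(t_ev); mm <- tot(m_ev); ss <- tot(shared)
  den <- tt + mm - ss
  if (den > 0) ss / den else NA_real_
}

oracle_sv_category_jaccard <- function(t_ev, m_ev, cat) {
  t_ev <- oracle_sv_dedupe(t_ev)
  m_ev <- oracle_sv_dedupe(m_ev)
  shared <- t_ev[oracle_sv_id(t_ev) %in% oracle_sv_id(m_ev), , drop = FALSE]
  tot <- function(ev) {
    s <- 0
    for (i in seq_len(nrow(ev)))
      if (ev$category[i] == cat)
        s <- s + if (cat == "TRA") 1 else ev$pos_b[i] - ev$pos_a[i]
    s
  }
  tt <- tot(t_ev); mm <- tot(m_ev); ss <- tot(shared)
  den <- tt + mm - ss
  if (tt + mm == 0) return(NULL)
  if (den > 0) ss / den else NA_real_
}

oracle_sv_weighted_count <- function(ev, chrom) {
  ev <- oracle_sv_dedupe(ev)
  s <- 0
  for (i in seq_len(nrow(ev))) {
    if (ev$category[i] == "TRA") {
      if (ev$chrom_a[i] == chrom) s <- s + 0.5
      if (ev$chrom_b[i] == chrom) s <- s + 0.5
    } else if (ev$chrom_a[i] == chrom) s <- s + 1
  }
  s
}

# per-base scan of two segment lists over a small genome (values already
# rescaled); returns list(T, X, C, I, G) for one chromosome set
oracle_cn_per_base <- function(a_segs, b_segs, genome, tolerance = 0.25,
                               chrom = NULL) {
  chroms <- if (is.null(chrom)) names(genome) else chrom
  T_ <- X_ <- C_ <- I_ <- 0
  for (ch in chroms) {
    len <- genome[[ch]]
    va <- rep(NA_real_, len)
    vb <- rep(NA_real_, len)
    aa <- a_segs[a_segs$chrom == ch, , drop = FALSE]
    bb <- b_segs[b_segs$chrom == ch, , drop = FALSE]
    for (i in seq_len(nrow(aa)))
      va[(aa$start[i] + 1):aa$end[i]] <- aa$imean[i]
    for (i in seq_len(nrow(bb)))
      vb[(bb$start[i] + 1):bb$end[i]] <- bb$imean[i]
    da <- !is.na(va); db <- !is.na(vb)
    T_ <- T_ + sum(da)
    X_ <- X_ + sum(db)
    C_ <- C_ + sum(da | db)
    both <- da & db
    I_ <- I_ + sum(both & abs(va - vb) <= tolerance, na.rm = TRUE)
  }
  den <- T_ + X_ - C_
  list(T = T_, X = X_, C = C_, I = I_,
       G = if (den > 0) I_ / den else NA_real_)
}

# ---- random small instances ------------------------------------------

random_call_set <- function(n, sample_id = "S", n_sites = 40,
                            types = c("Missense_Mutation", "Silent",
                                      "Intron", "IGR")) {
  pos <- sample.int(n_sites, n, replace = TRUE) * 10L
  refs <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  alts <- vapply(refs, function(r) sample(setdiff(c("A", "C", "G", "T"), r),
                                          1L), character(1))
  variant_calls(sample(c("chr1", "chr2", "chr3"), n, replace = TRUE),
                pos, refs, alts,
                sample(types, n, replace = TRUE), sample_id = sample_id)
}

# pair with controlled overlap: model reuses a slice of the tumour's calls
random_call_pair <- function(n_max = 100) {
  nt <- sample.int(n_max, 1L)
  t_calls <- random_call_set(nt, "T")
  n_keep <- sample.int(nt, 1L)
  kept <- t_calls[sample.int(nt, n_keep), , drop = FALSE]
  extra <- random_call_set(sample.int(n_max, 1L), "M")
  m_calls <- rbind(kept, extra)
  m_calls$sample_id <- rep("M", nrow(m_calls))
  class(m_calls) <- c("variant_calls", "data.frame")
  list(tumour = t_calls, model = m_calls)
}

random_sv_set <- function(n, sample_id = "S",
                          chroms = c("chr1", "chr2", "chr3", "chr4")) {
  if (n == 0) return(sv_events(sample_id = sample_id))
  rows <- lapply(seq_len(n), function(i) {
    if (stats::runif(1) < 0.25) {
      ch <- sample(chroms, 2L)
      data.frame(chrom_a = ch[1], pos_a = sample.int(1e6, 1L),
                 chrom_b = ch[2], pos_b = sample.int(1e6, 1L),
                 category = "TRA", stringsAsFactors = FALSE)
    } else {
      ch <- sample(chroms, 1L)
      p <- sort(sample.int(1e6, 2L))
      data.frame(chrom_a = ch, pos_a = p[1], chrom_b = ch, pos_b = p[2],
                 category = sample(c("DEL", "DUP", "INV"), 1L),
                 stringsAsFactors = FALSE)
    }
  })
  df <- do.call(rbind, rows)
  sv_events(df$chrom_a, df$pos_a, df$chrom_b, df$pos_b, df$category,
            sample_id = sample_id)
}

random_sv_pair <- function(n_max = 30) {
  nt <- sample.int(n_max, 1L)
  t_ev <- random_sv_set(nt, "T")
  n_keep <- sample.int(nt, 1L)
  kept <- t_ev[sample.int(nt, n_keep), , drop = FALSE]
  extra <- random_sv_set(sample.int(n_max, 1L), "M")
  m_ev <- rbind(kept, extra)
  m_ev$sample_id <- rep("M", nrow(m_ev))
  class(m_ev) <- c("sv_events", "data.frame")
  list(tumour = t_ev, model = m_ev)
}

# random segmentation of a tiny genome; a fraction of segments undefined
random_segmentation <- function(genome, sample_id = "S", max_segs = 6,
                                na_frac = 0.1) {
  out <- lapply(names(genome), function(ch) {
    len <- genome[[ch]]
    n_seg <- sample.int(max_segs, 1L)
    cuts <- sort(sample.int(len - 1L, n_seg - 1L))
    start <- c(0L, cuts)
    end <- c(cuts, len)
    keep <- stats::runif(n_seg) < 0.85  # leave some gaps uncovered
    imean <- sample(c(0.55, 1, 1.1, 1.35, 2.2), n_seg, replace = TRUE)
    imean[stats::runif(n_seg) < na_frac] <- NA_real_
    data.frame(chrom = ch, start = start, end = end, imean = imean,
               stringsAsFactors = FALSE)[keep, , drop = FALSE]
  })
  df <- do.call(rbind, out)
  cn_segments(df$chrom, df$start, df$end, df$imean, sample_id = sample_id)
}

toy_cn_genome <- c(chrA = 6000L, chrB = 4000L)
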