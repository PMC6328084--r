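# Copy-number concordance: rescaling, interval partition, the agreement
# score, ploidy QC.

seg <- function(chrom, start, end, imean, id = "S")
  cn_segments(chrom, start, end, imean, sample_id = id)

test_that("ploidy rescaling divides defined imean values and keeps NA", {
  s <- seg("chr1", c(0, 100, 200), c(100, 200, 300), c(2, 4, NA))
  r <- rescale_by_ploidy(s, 2)
  expect_equal(r$imean, c(1, 2, NA))
  expect_equal(rescale_by_ploidy(seg("chr1", 0, 10, 4), 3.8)$imean, 4 / 3.8)
  expect_error(rescale_by_ploidy(s, 0), "positive")
})

test_that("segment intersection partitions the union footprint into constant blocks", {
  a <- seg("chr1", 0, 100, 1.0, "A")
  b <- seg("chr1", 50, 150, 1.0, "B")
  blocks <- intersect_segments(a, b)
  expect_equal(blocks$start, c(0, 50, 100))
  expect_equal(blocks$end, c(50, 100, 150))
  expect_equal(is.na(blocks$value_b), c(TRUE, FALSE, FALSE))
  expect_equal(is.na(blocks$value_a), c(FALSE, FALSE, TRUE))
  # total block length equals the union footprint length
  expect_equal(sum(blocks$end - blocks$start), 150)
  # identical segmentations reproduce the input segments
  s2 <- seg("chr1", c(0, 100), c(100, 250), c(1, 2))
  blocks <- intersect_segments(s2, s2)
  expect_equal(blocks$start, c(0, 100))
  expect_equal(blocks$end, c(100, 250))
  expect_true(all(blocks$agrees))
})

test_that("concordance score is agreement over co-defined bases", {
  # identical profiles -> G = 1
  s <- seg("chr1", 0, 1e6, 1.0)
  expect_equal(cn_concordance(intersect_segments(s, s))$score, 1)
  # both defined, difference above tolerance everywhere -> 0
  a <- seg("chr1", 0, 1000, 1.0)
  b <- seg("chr1", 0, 1000, 1.3)
  expect_equal(cn_concordance(intersect_segments(a, b))$score, 0)
  # boundary: a difference of exactly 0.25 agrees
  b2 <- seg("chr1", 0, 1000, 1.25)
  expect_equal(cn_concordance(intersect_segments(a, b2))$score, 1)
  # half-overlapping profiles, equal on the overlap: T=200, X=200, C=300,
  # denominator T+X-C = co-defined 100 -> G = 1
  a <- seg("chr1", 0, 200, 1.0)
  b <- seg("chr1", 100, 300, 1.0)
  res <- cn_concordance(intersect_segments(a, b))
  expect_equal(res$t_bases, 200)
  expect_equal(res$m_bases, 200)
  expect_equal(res$union_bases, 300)
  expect_equal(res$score, 1)
  # the union denominator option dilutes by single-sample bases
  expect_equal(cn_concordance(intersect_segments(a, b),
                              denominator = "union")$score, 100 / 300)
  # nothing co-defined -> NA
  c_ <- seg("chr2", 0, 100, 1.0)
  expect_true(is.na(cn_concordance(intersect_segments(a, c_))$score))
})

test_that("NA imean segments count as covered but not defined", {
  a <- seg("chr1", c(0, 100), c(100, 200), c(1.0, NA))
  b <- seg("chr1", 0, 200, 1.0)
  res <- cn_concordance(intersect_segments(a, b))
  expect_equal(res$t_bases, 100)    # NA segment excluded from defined bases
  expect_equal(res$m_bases, 200)
  expect_equal(res$union_bases, 200)
  expect_equal(res$score, 1)        # the 100 co-defined bases agree
})

test_that("block decomposition and scores match a per-base brute-force scan", {
  set.seed(2024)
  for (i in 1:10) {
    a <- random_segmentation(toy_cn_genome, "A")
    b <- random_segmentation(toy_cn_genome, "B")
    blocks <- intersect_segments(a, b)
    want <- oracle_cn_per_base(a, b, toy_cn_genome)
    got <- cn_concordance(blocks)
    expect_identical(got$t_bases, as.numeric(want$T))
    expect_identical(got$m_bases, as.numeric(want$X))
    expect_identical(got$union_bases, as.numeric(want$C))
    expect_identical(got$agree_bases, as.numeric(want$I))
    expect_identical(got$score, want$G)
    for (ch in names(toy_cn_genome)) {
      want_ch <- oracle_cn_per_base(a, b, toy_cn_genome, chrom = ch)
      expect_identical(cn_concordance(blocks, scope = ch)$score, want_ch$G)
    }
  }
})

test_that("scores are invariant to joint imean/ploidy scaling and block splitting", {
  set.seed(77)
  a <- random_segmentation(toy_cn_genome, "A", na_frac = 0)
  b <- random_segmentation(toy_cn_genome, "B", na_frac = 0)
  base <- cn_concordance_table(intersect_segments(
    rescale_by_ploidy(a, 2), rescale_by_ploidy(b, 2)))
  for (k in c(2, 3.7)) {
    b_scaled <- b
    b_scaled$imean <- b$imean * k
    scaled <- cn_concordance_table(intersect_segments(
      rescale_by_ploidy(a, 2), rescale_by_ploidy(b_scaled, 2 * k)))
    expect_equal(scaled$score, base$score, tolerance = 1e-12)
  }
  # splitting a segment in two leaves every score unchanged
  split_first <- function(s) {
    r1 <- s[1, ]; mid <- floor((r1$start + r1$end) / 2)
    out <- rbind(
      data.frame(chrom = r1$chrom, start = r1$start, end = mid,
                 imean = r1$imean, sample_id = r1$sample_id),
      data.frame(chrom = r1$chrom, start = mid, end = r1$end,
                 imean = r1$imean, sample_id = r1$sample_id),
      s[-1, ]
    )
    class(out) <- c("cn_segments", "data.frame")
    out
  }
  split <- cn_concordance_table(intersect_segments(
    rescale_by_ploidy(split_first(a), 2), rescale_by_ploidy(b, 2)))
  expect_equal(split$score, base$score)
  # genome row aggregates numerators, not per-chromosome means
  per_chrom <- base[base$scope != "genome", ]
  expect_equal(base$score[base$scope == "genome"],
               sum(per_chrom$agree_bases) /
                 sum(per_chrom$t_bases + per_chrom$m_bases -
                       per_chrom$union_bases))
})

test_that("ploidy QC labels comparable, doubled, and ambiguous pairs", {
  expect_equal(ploidy_qc(1.9, 3.8), "doubled")
  expect_equal(ploidy_qc(2.0, 2.1), "comparable")
  expect_equal(ploidy_qc(2.0, 3.0), "ambiguous")
  expect_equal(ploidy_qc(3.8, 1.9), "doubled")  # orientation-free
  expect_equal(ploidy_qc(sample_ploidy("a", 2), sample_ploidy("b", 2)),
               "comparable")
})
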