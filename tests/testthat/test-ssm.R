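# Mutation-set concordance: identity keys, per-category and overall
# Jaccard, VAF, driver-gene tallies.

test_that("variant identity is chromosome + position + substitution", {
  a <- variant_calls("chr12", 25398284, "C", "T", "Missense_Mutation")
  b <- variant_calls("chr12", 25398284, "C", "T", "Silent")  # relabelled
  c_ <- variant_calls("chr12", 25398284, "C", "A", "Missense_Mutation")
  d <- variant_calls("chr12", 25398284, "CT", "C", "Frame_Shift_Del")
  expect_equal(variant_identity_key(a), variant_identity_key(b))
  expect_false(variant_identity_key(a) == variant_identity_key(c_))
  expect_false(variant_identity_key(a) == variant_identity_key(d))
})

make_set <- function(n, type = "Missense_Mutation", offset = 0) {
  variant_calls("chr1", seq_len(n) + offset, "A", "T", type, sample_id = "S")
}

test_that("per-category Jaccard follows C/(T+P-C) with NA for absent categories", {
  # T=10, P=12, C=8 -> 8/14
  t_calls <- make_set(10)
  m_calls <- make_set(12, offset = 2)  # positions 3..14: 8 shared
  row <- jaccard_by_type(t_calls, m_calls)
  expect_equal(row$t_count, 10)
  expect_equal(row$m_count, 12)
  expect_equal(row$shared, 8)
  expect_equal(row$jaccard, 8 / 14)

  # identical call sets: J = 1 per category
  rows <- jaccard_by_type(t_calls, t_calls)
  expect_true(all(rows$jaccard == 1))

  # a category present in only one sample scores 0, never NA; categories in
  # neither sample are not emitted
  t2 <- rbind(make_set(5), make_set(3, type = "Silent", offset = 100))
  class(t2) <- c("variant_calls", "data.frame")
  rows <- jaccard_by_type(t2, make_set(5))
  expect_equal(rows$jaccard[rows$mutation_type == "Silent"], 0)
  expect_false("Intron" %in% rows$mutation_type)
})

test_that("within-sample duplicate calls collapse before counting", {
  t_calls <- rbind(make_set(5), make_set(5))  # every key twice
  class(t_calls) <- c("variant_calls", "data.frame")
  row <- jaccard_by_type(t_calls, make_set(5))
  expect_equal(row$t_count, 5)
  expect_equal(row$jaccard, 1)
})

test_that("overall Jaccard spans all categories and handles limits", {
  t_calls <- rbind(make_set(50), make_set(25, "Silent", offset = 1000))
  class(t_calls) <- c("variant_calls", "data.frame")
  # tumour set strictly inside model set: J = |T|/|M|
  m_calls <- rbind(t_calls,
                   make_set(75, "Intron", offset = 5000))
  class(m_calls) <- c("variant_calls", "data.frame")
  expect_equal(jaccard_all_mutations(t_calls, m_calls)$jaccard, 0.5)
  # disjoint nonempty sets -> 0
  expect_equal(jaccard_all_mutations(make_set(10),
                                     make_set(10, offset = 100))$jaccard, 0)
  # both empty -> NA with zero counts
  empty <- variant_calls()
  row <- jaccard_all_mutations(empty, empty)
  expect_true(is.na(row$jaccard))
  expect_equal(row$t_count + row$m_count, 0)
})

test_that("Jaccard matches a brute-force set oracle on random pairs and is symmetric", {
  set.seed(42)
  for (i in 1:25) {
    pair <- random_call_pair(50)
    rows <- jaccard_by_type(pair$tumour, pair$model)
    for (k in seq_len(nrow(rows))) {
      ty <- rows$mutation_type[k]
      t_keys <- variant_identity_key(pair$tumour)[
        pair$tumour$mutation_type == ty]
      m_keys <- variant_identity_key(pair$model)[
        pair$model$mutation_type == ty]
      expect_identical(rows$jaccard[k], oracle_set_jaccard(t_keys, m_keys))
    }
    expect_identical(
      jaccard_all_mutations(pair$tumour, pair$model)$jaccard,
      oracle_set_jaccard(variant_identity_key(pair$tumour),
                         variant_identity_key(pair$model))
    )
    # symmetry and input-order invariance
    flipped <- jaccard_by_type(pair$model, pair$tumour)
    expect_equal(rows$jaccard,
                 flipped$jaccard[match(rows$mutation_type,
                                       flipped$mutation_type)])
    shuf <- pair$tumour[sample.int(nrow(pair$tumour)), , drop = FALSE]
    class(shuf) <- c("variant_calls", "data.frame")
    expect_equal(jaccard_by_type(shuf, pair$model)$jaccard, rows$jaccard)
  }
})

test_that("variant-allele fraction handles depths and missingness", {
  calls <- variant_calls(rep("chr1", 4), 1:4, "A", "T", "Silent",
                         ref_depth = c(30L, 40L, 0L, NA),
                         alt_depth = c(30L, 0L, 0L, NA))
  expect_equal(variant_allele_fraction(calls), c(0.5, 0, NA, NA))
})

test_that("driver panel tallies mutation types per gene with inclusive bounds", {
  panel <- data.frame(gene = c("KRAS", "TP53"),
                      chrom = c("chr12", "chr17"),
                      start = c(100L, 500L), end = c(200L, 600L))
  calls <- variant_calls(
    c("chr12", "chr12", "chr17", "chr1"),
    c(150L, 200L, 499L, 150L),           # 200 = boundary, 499 = just out
    "A", "T",
    c("Missense_Mutation", "Silent", "Missense_Mutation", "Intron"),
    sample_id = "S1"
  )
  tab <- driver_panel_summary(calls, panel)
  expect_equal(tab["KRAS", "S1"], "Missense_Mutation,Silent")
  expect_equal(tab["TP53", "S1"], "")
  expect_error(
    driver_panel_summary(calls, data.frame(gene = "X", chrom = "chr1",
                                           start = 10L, end = 5L)),
    "malformed"
  )
  # no calls in any interval: all-empty table
  none <- driver_panel_summary(variant_calls(sample_id = "S1"), panel)
  expect_true(all(none == ""))
})
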