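# The synthetic matched-callset generator: construction guarantees,
# determinism, truth records.

test_that("mutation pair realizes the requested shared/private structure", {
  sc <- pair_scenario(seed = 5, ssm = list(n_shared = 70L,
                                           n_tumour_only = 30L,
                                           n_model_only = 30L))
  res <- simulate_pair_ssm(sc)
  expect_equal(nrow(res$tumour), 100)
  expect_equal(nrow(res$model), 100)
  tk <- variant_identity_key(res$tumour)
  mk <- variant_identity_key(res$model)
  expect_equal(length(intersect(tk, mk)), 70)
  expect_equal(res$truth$overall, 70 / 130)
  # no shared variants: J = 0
  sc0 <- pair_scenario(seed = 5, ssm = list(n_shared = 0L,
                                            n_tumour_only = 10L,
                                            n_model_only = 10L))
  expect_equal(simulate_pair_ssm(sc0)$truth$overall, 0)
})

test_that("generators are pure functions of scenario and seed", {
  sc <- pair_scenario(seed = 9)
  a <- simulate_pair_ssm(sc)
  b <- simulate_pair_ssm(sc)
  expect_identical(a, b)
  expect_identical(simulate_pair_sv(sc), simulate_pair_sv(sc))
  expect_identical(simulate_pair_cn(sc), simulate_pair_cn(sc))
  d1 <- tempfile(); d2 <- tempfile()
  simulate_trio(sc, out_dir = d1)
  simulate_trio(sc, out_dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
  }
})

test_that("clustered chromosome carries a confined, fully shared event cluster", {
  sc <- pair_scenario(seed = 13)
  res <- simulate_pair_sv(sc)
  chr8_t <- res$tumour[res$tumour$chrom_a == "chr8" &
                         res$tumour$category != "TRA", ]
  expect_gte(nrow(chr8_t), 5)
  expect_lte(max(chr8_t$pos_b) - min(chr8_t$pos_a), 5e6)
  expect_equal(res$truth$chrom_jaccard[["chr8"]], 1)
  expect_gte(res$truth$t_counts[["chr8"]], 5)
  expect_gte(res$truth$m_counts[["chr8"]], 5)
})

test_that("an asymmetric cluster drives discordance flags, not concordance", {
  # cluster present only in the model: J = 0 there, and a >=10 count gap
  prof <- data.frame(chrom = "chr22", n_shared = 0L, n_tumour_only = 0L,
                     n_model_only = 12L, clustered = TRUE)
  sc <- pair_scenario(seed = 17, sv = prof,
                      sv_tra = list(n_shared = 0L, n_tumour_only = 0L,
                                    n_model_only = 0L))
  res <- simulate_pair_sv(sc)
  expect_equal(res$truth$chrom_jaccard[["chr22"]], 0)
  tab <- sv_chromosome_table(res$tumour, res$model)
  row <- tab[tab$chrom == "chr22", ]
  expect_false(row$elevated)
  expect_true(row$discordant_count)
})

test_that("copy-number pair honours ploidy factor and discordant fraction", {
  sc <- pair_scenario(seed = 29, cn = list(discordant_fraction = 0))
  res <- simulate_pair_cn(sc)
  expect_equal(res$model$ploidy$ploidy, res$tumour$ploidy$ploidy * 2)
  expect_equal(res$truth$genome, 1)   # ploidy-doubling alone costs nothing
  sc2 <- pair_scenario(seed = 29, cn = list(ploidy_factor = 1, jitter = 0,
                                            discordant_fraction = 0))
  res2 <- simulate_pair_cn(sc2)
  expect_equal(res2$truth$genome, 1)
  expect_equal(res2$tumour$segments$imean, res2$model$segments$imean)
  # requested discordance shows up in the truth record
  sc3 <- pair_scenario(seed = 29, cn = list(discordant_fraction = 0.3))
  g <- simulate_pair_cn(sc3)$truth$genome
  expect_lt(g, 1)
  expect_gt(g, 0.4)
  expect_error(pair_scenario(cn = list(jitter = 0.2)), "incompatible")
})

test_that("hypermutator scenarios scale mutation counts only", {
  sc <- pair_scenario(seed = 41, hypermutator = TRUE,
                      hypermutator_factor = 5)
  expect_equal(sc$ssm$n_shared, 3500L)
  res <- simulate_pair_ssm(sc)
  expect_equal(nrow(res$tumour), 5000)
  expect_equal(res$truth$overall, 3500 / 6500)  # ratio unchanged
  expect_identical(sc$sv, default_sv_profile())
})

test_that("running the pipeline on emitted files reproduces the truth record", {
  dir <- tempfile()
  tr <- simulate_trio(pair_scenario(seed = 37), out_dir = dir)
  rep <- run_patient(read_manifest(file.path(dir, "manifest.yaml"))[[1]])
  for (pl in c("TvsX", "TvsO", "XvsO")) {
    got <- rep$pair_results[[pl]]
    want <- tr$truth[[pl]]
    expect_equal(got$ssm$overall$jaccard, want$ssm$overall)
    merged <- merge(got$ssm$by_type, want$ssm$by_type, by = "mutation_type")
    expect_equal(merged$jaccard.x, merged$jaccard.y)
    jv <- stats::setNames(got$sv$chrom_rows$jaccard, got$sv$chrom_rows$chrom)
    expect_equal(jv[names(want$sv$chrom_jaccard)], want$sv$chrom_jaccard)
    expect_equal(got$sv$overall$score, want$sv$sc)
    expect_equal(got$cn$table$score[got$cn$table$scope == "genome"],
                 want$cn$genome)
  }
  # organoid derived from the PDX: model-model concordance beats
  # tumour-organoid concordance
  expect_gte(tr$truth$XvsO$ssm$overall, tr$truth$TvsO$ssm$overall)
})
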