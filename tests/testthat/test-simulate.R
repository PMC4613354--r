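test_that("simulation is deterministic given the seed", {
  p <- genome_sim_params(length = 20000, seed = 99)
  a <- simulate_genome(p)
  b <- simulate_genome(p)
  expect_identical(a$record$sequence, b$record$sequence)
  expect_identical(a$record$genes, b$record$genes)
  expect_identical(a$cog, b$cog)
  expect_identical(a$kegg, b$kegg)

  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  co1 <- simulate_cohort(cohort_sim_params(n_genomes = 4, seed = 5,
                                           mean_length = 20000), d1)
  co2 <- simulate_cohort(cohort_sim_params(n_genomes = 4, seed = 5,
                                           mean_length = 20000), d2)
  files <- list.files(d1, recursive = TRUE)
  expect_identical(files, list.files(d2, recursive = TRUE))
  for (f in files) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})

test_that("null deltas give a near-zero score and planted deltas are recovered", {
  null <- simulate_genome(genome_sim_params(length = 1e6, delta_gc = 0,
                                            delta_ta = 0, seed = 3))
  s0 <- composition_bias_score(leading_strand_counts(null$record), 1e6)
  # |G-C|+|T-A| of a fair strand folds noise: stays within a few mean deviations
  expect_lt(s0, 5 * sqrt(2 * 0.5 / 1e6))

  planted <- simulate_genome(genome_sim_params(length = 1e6, delta_gc = 0.03,
                                               delta_ta = 0.02, seed = 4))
  s1 <- composition_bias_score(leading_strand_counts(planted$record), 1e6)
  expect_lt(abs(s1 - 0.05), 3 * sqrt(2 * 0.5 / 1e6))
})

test_that("invalid simulation parameters are named in the error", {
  expect_error(genome_sim_params(gc_target = 0.3, delta_gc = 0.4),
               regexp = "C", class = "strandbias_error_params")
  expect_error(genome_sim_params(leading_prob = 1.2),
               class = "strandbias_error_params")
})

test_that("gene packing beyond 90% of the chromosome errors", {
  p <- genome_sim_params(length = 10000, n_genes = 20,
                         gene_length = c(900, 1000))
  expect_error(simulate_genome(p), class = "strandbias_error_packing")
})

test_that("inversions: identity at n = 0 and involution on a fixed segment", {
  sim <- simulate_genome(genome_sim_params(length = 30000, seed = 17))
  expect_identical(apply_inversions(sim$record, 0), sim$record)

  rec <- sim$record
  once <- apply_inversions(rec, 1, length_range = c(4000, 4000), seed = 8)
  expect_false(identical(once$sequence, rec$sequence))
  # re-apply the same event (same seed -> same segment): sequence restored
  twice <- apply_inversions(once, 1, length_range = c(4000, 4000), seed = 8)
  expect_identical(twice$sequence, rec$sequence)
})

test_that("inverted segments never contain ori or ter", {
  sim <- simulate_genome(genome_sim_params(length = 50000, seed = 23,
                                           n_inversions = 10))
  # replichore map still valid and genes consistent
  m <- replichore_map(sim$record$ori, sim$record$ter, sim$record$length)
  expect_s3_class(classify_genes(sim$record$genes, m), "tbl_df")
  expect_true(all(sim$record$genes$end <= sim$record$length))
})

test_that("inversions scatter per-gene skews: score drops, gcRF rises", {
  # small version of the trend (full version in the acceptance suite)
  stats_at <- function(n_inv, seed) {
    sim <- simulate_genome(genome_sim_params(length = 200000, seed = seed,
                                             delta_gc = 0.04, delta_ta = 0.02,
                                             n_inversions = n_inv))
    f <- suppressMessages(genome_features(sim$record))
    c(score = f$score, gcRF = f$gcRF)
  }
  res0 <- colMeans(t(sapply(1:6, function(s) stats_at(0, s))))
  res32 <- colMeans(t(sapply(1:6, function(s) stats_at(32, s))))
  expect_lt(res32["score"], res0["score"])
  expect_gt(res32["gcRF"], res0["gcRF"])
})

test_that("cohort ground truth matches recomputed features within Monte-Carlo error", {
  co <- simulate_cohort(cohort_sim_params(n_genomes = 12, seed = 31,
                                          mean_length = 150000))
  feats <- suppressWarnings(cohort_features(co))
  j <- dplyr::inner_join(feats, co$truth, by = "genome_id")
  # expected score = delta_gc + delta_ta; per-genome 3-sigma binomial bound
  se <- sqrt(2 * 0.5 / j$genome_size)
  expect_true(all(abs(j$score - j$delta_sum) < 4 * se))
  expect_true(all(abs(j$gc_content - j$gc_target) < 4 * sqrt(0.25 / j$genome_size)))
  n_genes <- vapply(co$genomes[j$genome_id],
                    function(r) nrow(r$genes), integer(1))
  expect_true(all(abs(j$gene_density_leading - j$leading_prob) <
                    4 * sqrt(0.25 / n_genes)))
})

test_that("null cohorts carry no planted feature couplings", {
  p <- cohort_sim_params(n_genomes = 10, seed = 1, effects = "null")
  expect_equal(p$beta_density, 0)
  expect_equal(p$beta_gc, 0)
  expect_equal(p$beta_size, 0)
  expect_equal(p$cog_coupling, 0)
  expect_equal(p$obligate_offset, 0)
  co <- simulate_cohort(p)
  expect_equal(unique(co$truth$delta_sum), p$delta_null)
})
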