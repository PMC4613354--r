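test_that("Spearman handles monotone vectors, ties, and degenerate input", {
  expect_equal(spearman_test(1:4, c(10, 20, 30, 40))$rho, 1)
  expect_equal(spearman_test(1:4, c(40, 30, 20, 10))$rho, -1)
  expect_warning(r <- spearman_test(1:5, rep(2, 5)), "zero variance")
  expect_true(is.na(r$rho))
  expect_error(spearman_test(1:2, 2:1), class = "strandbias_error_undefined")
  # missing values removed pairwise
  expect_equal(spearman_test(c(1, 2, NA, 4, 5), c(2, 4, 9, 8, 10))$n_pairs, 4)
})

test_that("Spearman rho equals rank-then-Pearson on tied vectors", {
  set.seed(8)
  for (i in 1:50) {
    n <- sample(4:12, 1)
    x <- sample(1:5, n, replace = TRUE)   # heavy ties
    y <- sample(1:5, n, replace = TRUE)
    if (sd(x) == 0 || sd(y) == 0) next
    expect_equal(spearman_test(x, y)$rho, brute_spearman_rho(x, y),
                 tolerance = 1e-12)
  }
})

test_that("Spearman is invariant under strictly monotone transforms", {
  set.seed(15)
  for (i in 1:10) {
    x <- rnorm(30); y <- rnorm(30)
    base <- spearman_test(x, y)$rho
    expect_equal(spearman_test(exp(x), y)$rho, base)
    expect_equal(spearman_test(x, y^3)$rho, base)
  }
})

test_that("exact permutation p-value agrees with the asymptotic one in rank order", {
  x <- c(1, 2, 3, 4, 5); y <- c(2, 1, 4, 3, 5)
  ex <- spearman_test(x, y, p_method = "exact")
  expect_gte(ex$p_value, 0)
  expect_lte(ex$p_value, 1)
  # perfect monotone association is the most extreme permutation
  expect_equal(spearman_test(x, sort(y), p_method = "exact")$p_value,
               2 / factorial(5), tolerance = 1e-12)
})

test_that("group comparison reports Welch t-test means and p-values", {
  same <- c(1, 2, 3, 4)
  r <- group_t_test(same, same)
  expect_equal(r$t_statistic, 0)
  expect_equal(r$p_value, 1)

  g1 <- rnorm(30) + 100
  g2 <- rnorm(30)
  expect_lt(group_t_test(g1, g2)$p_value, 1e-6)
  expect_error(group_t_test(1, c(1, 2)), class = "strandbias_error_undefined")
})

test_that("obligate-intracellular genomes with planted offset score higher", {
  co <- simulate_cohort(cohort_sim_params(n_genomes = 100, seed = 21,
                                          mean_length = 50000,
                                          obligate_rate = 0.5))
  feats <- suppressWarnings(cohort_features(co))
  g1 <- feats$score[feats$obligate_intracellular]
  g2 <- feats$score[!feats$obligate_intracellular]
  r <- group_t_test(g1, g2)
  expect_gt(r$mean_group1, r$mean_group2)
  expect_lt(r$p_value, 0.05)
})

test_that("phylum summaries report grouped moments with singleton NA", {
  f <- tibble::tibble(phylum = c("A", "A", "B"),
                      score = c(0.1, 0.3, 0.2))
  s <- phylum_summaries(f)
  expect_equal(s$mean_score, c(0.2, 0.2))
  expect_equal(s$sd_score[1], sqrt(0.02))
  expect_equal(s$var_score[1], 0.02)
  expect_true(is.na(s$sd_score[2]))
  expect_true(is.na(s$var_score[2]))

  # brute-force group-by oracle on a random cohort
  set.seed(2)
  f2 <- tibble::tibble(phylum = sample(c("P1", "P2", "P3"), 40, replace = TRUE),
                       score = runif(40), genome_size = runif(40, 1e5, 1e6))
  s2 <- phylum_summaries(f2)
  for (p in unique(f2$phylum)) {
    expect_equal(s2$mean_score[s2$phylum == p], mean(f2$score[f2$phylum == p]))
    expect_equal(s2$mean_genome_size[s2$phylum == p],
                 mean(f2$genome_size[f2$phylum == p]))
  }
})

test_that("PCR identity case attributes all of R2 to the matching feature", {
  # orthogonal design: centered orthonormal columns (orthogonal in sample)
  set.seed(101)
  q <- qr.Q(qr(cbind(1, matrix(rnorm(40 * 4), 40, 4))))[, 2:5]
  colnames(q) <- paste0("f", 1:4)
  fit <- pcr_decomposition(q, q[, 1])
  expect_equal(unname(fit$contributions["f1"]), 1, tolerance = 1e-9)
  expect_equal(unname(fit$contributions[c("f2", "f3", "f4")]), rep(0, 3),
               tolerance = 1e-9)
  expect_equal(fit$total_r2, 1, tolerance = 1e-9)
})

test_that("PCR total R2 is near zero for independent noise", {
  set.seed(33)
  X <- matrix(rnorm(500 * 3), 500, 3, dimnames = list(NULL, paste0("f", 1:3)))
  fit <- pcr_decomposition(X, rnorm(500))
  expect_lt(fit$total_r2, 0.05)
})

test_that("PCR contributions sum to the OLS R2 on components", {
  set.seed(44)
  for (i in 1:50) {
    X <- matrix(rnorm(50 * 5), 50, 5, dimnames = list(NULL, paste0("f", 1:5)))
    y <- rnorm(50)
    fit <- pcr_decomposition(X, y)
    expect_true(all(fit$contributions >= -1e-12))
    expect_equal(sum(fit$contributions), fit$total_r2, tolerance = 1e-9)
    # independent oracle: ordinary least squares of y on the standardised X
    # (same span as all principal components)
    ols <- summary(lm(y ~ scale(X)))$r.squared
    expect_equal(fit$total_r2, ols, tolerance = 1e-9)
  }
})

test_that("PCR contribution vector is stable under reordering and rescaling", {
  set.seed(55)
  X <- matrix(rnorm(60 * 4), 60, 4, dimnames = list(NULL, paste0("f", 1:4)))
  y <- X %*% c(1, -0.5, 0, 0.2) + rnorm(60, sd = 0.5)
  base <- pcr_decomposition(X, y)$contributions
  perm <- c(3, 1, 4, 2)
  reord <- pcr_decomposition(X[, perm], y)$contributions
  expect_equal(unname(reord[paste0("f", 1:4)]), unname(base),
               tolerance = 1e-9)
  Xs <- sweep(X, 2, c(10, 0.1, 3, 1000), `*`)
  rescaled <- pcr_decomposition(Xs, y)$contributions
  expect_equal(unname(rescaled), unname(base), tolerance = 1e-9)
})

test_that("PCR validates shape and drops incomplete rows listwise", {
  X <- matrix(rnorm(30), 15, 2, dimnames = list(NULL, c("a", "b")))
  X[3, 1] <- NA
  expect_message(fit <- pcr_decomposition(X, rnorm(15)), "dropping 1 row")
  expect_equal(fit$n, 14)
  expect_equal(fit$dropped_rows, 1)
  expect_error(pcr_decomposition(X[, 1, drop = FALSE], rnorm(15)),
               class = "strandbias_error_invalid")
})

test_that("tidy and glance expose the PCR decomposition as tibbles", {
  set.seed(66)
  X <- matrix(rnorm(80), 40, 2, dimnames = list(NULL, c("a", "b")))
  fit <- pcr_decomposition(X, rnorm(40))
  td <- tidy(fit)
  expect_equal(td$feature, c("a", "b"))
  expect_equal(sum(td$r_squared), glance(fit)$total_r2)
  expect_equal(glance(fit)$n, 40)
})

test_that("correlation battery annotates both significance conventions", {
  set.seed(77)
  n <- 120
  f <- tibble::tibble(
    score = runif(n),
    up = NA_real_, down = NA_real_, noise = rnorm(n), flat = 1)
  f$up <- f$score + rnorm(n, sd = 0.05)
  f$down <- -2 * f$score + rnorm(n, sd = 0.05)
  expect_warning(b <- correlation_battery(f), "zero variance")
  expect_gt(b$rho[b$feature == "up"], 0)
  expect_lt(b$rho[b$feature == "down"], 0)
  expect_true(b$significant_strict[b$feature == "up"])
  expect_true(is.na(b$rho[b$feature == "flat"]))
})
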