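toy_cog <- function(genomes, genes_per, letter) {
  purrr::map_dfr(seq_along(genomes), function(i) {
    tibble::tibble(genome_id = genomes[i],
                   gene_id = sprintf("%s_g%02d", genomes[i],
                                     seq_len(genes_per[i])),
                   cog_group_id = paste0("COG_", letter[i], "01"),
                   subcategories = letter[i])
  })
}

test_that("pCOG drops R/S/X, counts per letter, and normalises", {
  a <- tibble::tibble(gene_id = sprintf("g%02d", 1:25),
                      subcategories = c(rep("J", 10), rep("C", 10), rep("R", 5)))
  p <- pcog(a)
  expect_equal(p$fraction[p$subcategory == "J"], 0.5)
  expect_equal(p$fraction[p$subcategory == "C"], 0.5)
  expect_false("R" %in% p$subcategory)
  expect_equal(sum(p$fraction), 1)

  two <- pcog(tibble::tibble(gene_id = "g1", subcategories = "KL"))
  expect_equal(two$fraction[two$subcategory == "K"], 0.5)
  expect_equal(two$fraction[two$subcategory == "L"], 0.5)

  expect_error(pcog(tibble::tibble(gene_id = "g1", subcategories = "S")),
               class = "strandbias_error_undefined")
})

test_that("pCOG matches a brute-force tally on random assignment tables", {
  set.seed(31)
  for (i in 1:20) {
    n <- sample(5:60, 1)
    letters_drawn <- replicate(n, paste(sample(LETTERS, sample(1:3, 1)),
                                        collapse = ""))
    a <- tibble::tibble(gene_id = sprintf("g%03d", 1:n),
                        subcategories = letters_drawn)
    split_letters <- unlist(strsplit(letters_drawn, ""))
    kept <- split_letters[!split_letters %in% c("R", "S", "X")]
    if (length(kept) == 0) next
    p <- pcog(a)
    expect_equal(sum(p$fraction), 1)
    tally <- table(factor(kept, levels = COG_LETTERS))
    expect_equal(p$n, unname(as.integer(tally)))
  }
})

test_that("cohort split takes the top half by score with deterministic ties", {
  s <- tibble::tibble(genome_id = c("d", "c", "b", "a"), score = c(1, 2, 3, 4))
  sp <- split_cohort(s)
  expect_equal(sort(sp$genome_id[sp$bias_group == "SBG"]), c("a", "b"))

  # N = 1111 -> 555 strong-biased genomes
  big <- tibble::tibble(genome_id = sprintf("g%04d", 1:1111),
                        score = seq(0, 0.2, length.out = 1111))
  spb <- split_cohort(big)
  expect_equal(sum(spb$bias_group == "SBG"), 555)
  expect_equal(sum(spb$bias_group == "WBG"), 556)

  ties <- tibble::tibble(genome_id = sprintf("g%d", 6:1), score = rep(1, 6))
  spt <- split_cohort(ties)
  expect_equal(sort(spt$genome_id[spt$bias_group == "SBG"]),
               c("g1", "g2", "g3"))
  expect_identical(split_cohort(ties), split_cohort(ties))
  expect_error(split_cohort(ties[1, ]), class = "strandbias_error_undefined")
})

test_that("strong/weak count ratios follow the declared zero policy", {
  cog <- toy_cog(c("s1", "s2", "w1", "w2"), c(10, 10, 5, 5),
                 c("J", "J", "J", "J"))
  cog2 <- toy_cog("s1", 7, "K")  # group absent from WBG
  split <- tibble::tibble(genome_id = c("s1", "s2", "w1", "w2"),
                          score = c(4, 3, 2, 1),
                          bias_group = c("SBG", "SBG", "WBG", "WBG"))
  expect_warning(r <- diff_ratios(dplyr::bind_rows(cog, cog2), split),
                 "absent from the weak-biased group")
  expect_equal(nrow(r), 1)
  expect_equal(r$ratio, 20 / 10)

  # zero numerator is a plain 0, not excluded
  cog3 <- toy_cog(c("w1", "w2"), c(4, 3), c("L", "L"))
  r3 <- suppressWarnings(diff_ratios(dplyr::bind_rows(cog, cog3), split))
  expect_equal(r3$ratio[r3$cog_group_id == "COG_L01"], 0)

  # pseudocount alternative keeps the zero-denominator group
  rp <- diff_ratios(dplyr::bind_rows(cog, cog2), split, pseudocount = 1)
  expect_equal(rp$ratio[rp$cog_group_id == "COG_K01"], 8 / 1)
})

test_that("ratios are invariant to scaling both groups' counts", {
  cog <- dplyr::bind_rows(
    toy_cog(c("s1", "w1"), c(6, 3), c("J", "J")),
    toy_cog(c("s1", "w1"), c(4, 8), c("D", "D")))
  split3 <- tibble::tibble(genome_id = c("s1", "w1"), score = c(2, 1),
                           bias_group = c("SBG", "WBG"))
  r1 <- diff_ratios(cog, split3)
  cog_x3 <- dplyr::bind_rows(cog, dplyr::mutate(cog, gene_id = paste0(gene_id, "b")),
                             dplyr::mutate(cog, gene_id = paste0(gene_id, "c")))
  r3 <- diff_ratios(cog_x3, split3)
  expect_equal(r1$ratio, r3$ratio)
})

test_that("AVDT is the per-subcategory mean of group ratios", {
  r <- tibble::tibble(cog_group_id = c("COG_J01", "COG_J02", "COG_D01"),
                      subcategories = c("J", "J", "D"),
                      n_sbg = c(2, 4, 3), n_wbg = c(1, 1, 1),
                      ratio = c(2, 4, 3))
  a <- suppressWarnings(avdt(r))
  expect_equal(a$avdt[a$subcategory == "J"], 3)
  expect_equal(a$avdt[a$subcategory == "D"], 3)
  expect_equal(a$n_groups[a$subcategory == "J"], 2)

  # multi-letter group contributes to both letters; constant ratio r -> avdt r
  rm <- tibble::tibble(cog_group_id = c("COG_KL1", "COG_K01"),
                       subcategories = c("KL", "K"),
                       n_sbg = c(5, 5), n_wbg = c(1, 1), ratio = c(5, 5))
  am <- suppressWarnings(avdt(rm))
  expect_equal(am$avdt[am$subcategory == "K"], 5)
  expect_equal(am$avdt[am$subcategory == "L"], 5)

  # brute-force mean-by-group oracle on random tables
  set.seed(12)
  for (i in 1:10) {
    n <- sample(4:30, 1)
    letters_drawn <- sample(COG_LETTERS, n, replace = TRUE)
    rr <- tibble::tibble(cog_group_id = sprintf("COG_%s%02d", letters_drawn, 1:n),
                         subcategories = letters_drawn,
                         n_sbg = 1, n_wbg = 1,
                         ratio = round(runif(n, 0, 8), 3))
    got <- suppressWarnings(avdt(rr))
    want <- tapply(rr$ratio, rr$subcategories, mean)
    expect_equal(got$avdt[order(got$subcategory)],
                 as.numeric(want[sort(names(want))]))
  }
})

test_that("SCOG/WCOG selection applies the > 5 and < 0.2 thresholds", {
  r <- tibble::tibble(cog_group_id = c("g1", "g2", "g3"),
                      subcategories = c("D", "J", "Q"),
                      n_sbg = c(6, 1, 1), n_wbg = c(1, 1, 10),
                      ratio = c(6, 1, 0.1))
  sets <- select_scog_wcog(r)
  expect_equal(sets$scog_ids, "g1")
  expect_equal(sets$wcog_ids, "g3")
  expect_length(intersect(sets$scog_ids, sets$wcog_ids), 0)

  empty <- select_scog_wcog(r[0, ])
  expect_length(empty$scog_ids, 0)
  expect_length(empty$wcog_ids, 0)
})

test_that("per-genome SCOG/WCOG proportions use COG-annotated genes", {
  cog <- tibble::tibble(
    genome_id = "g", gene_id = sprintf("gene%02d", 1:10),
    cog_group_id = c(rep("strong", 4), rep("plain", 4), rep("weak", 2)),
    subcategories = "J")
  sets <- structure(list(scog_ids = "strong", wcog_ids = "weak"),
                    class = "cog_group_sets")
  pr <- genome_group_proportions(cog, sets)
  expect_equal(pr$scog_fraction, 0.4)
  expect_equal(pr$wcog_fraction, 0.2)

  none <- structure(list(scog_ids = character(), wcog_ids = character()),
                    class = "cog_group_sets")
  pr0 <- genome_group_proportions(cog, none)
  expect_equal(c(pr0$scog_fraction, pr0$wcog_fraction), c(0, 0))
})

test_that("pathway proportions cover the ten pathways and reject unknown ids", {
  kegg <- tibble::tibble(gene_id = sprintf("g%02d", 1:5),
                         pathway_id = rep("ko03430", 5))
  pp <- pathway_proportions(kegg, n_genes = 100)
  expect_equal(nrow(pp), 10)
  expect_equal(pp$fraction[pp$pathway_id == "ko03430"], 0.05)
  expect_equal(sum(pp$fraction[pp$pathway_id != "ko03430"]), 0)

  empty <- pathway_proportions(kegg[0, ], n_genes = 50)
  expect_equal(empty$fraction, rep(0, 10))

  expect_error(pathway_proportions(
    tibble::tibble(gene_id = "g1", pathway_id = "ko99999"), 10),
    regexp = "ko99999", class = "strandbias_error_parse")

  # brute-force tally on random tables
  set.seed(4)
  for (i in 1:10) {
    n <- sample(1:40, 1)
    k <- tibble::tibble(gene_id = sprintf("g%03d", 1:n),
                        pathway_id = sample(KEGG_RR_PATHWAYS, n, replace = TRUE))
    got <- pathway_proportions(k, n_genes = 200)
    want <- table(factor(k$pathway_id, levels = KEGG_RR_PATHWAYS)) / 200
    expect_equal(got$fraction, unname(as.numeric(want)))
  }
})
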