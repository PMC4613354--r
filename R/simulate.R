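# Synthetic circular bacterial genomes with known strand-bias structure.

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Parameters for one simulated genome
#'
#' The generative model is site-independent on the leading strand: each
#' leading-strand position is G with probability `gc_target/2 + delta_gc/2`,
#' C with `gc_target/2 - delta_gc/2`, T with
#' `(1 - gc_target)/2 + delta_ta/2`, A with `(1 - gc_target)/2 - delta_ta/2`.
#' The published strand equals the leading strand over arc 1 (`[ori, ter)`)
#' and its complement over arc 2, so with no inversions the expected
#' composition-bias score is `|delta_gc| + |delta_ta|`. Non-overlapping
#' genes are placed uniformly and oriented onto the leading strand with
#' probability `leading_prob` (optionally shifted per COG subcategory via
#' `cog_leading_coupling`).
#'
#' @param genome_id Identifier written into all outputs.
#' @param seed Integer RNG seed; every draw is deterministic given it.
#' @param length Chromosome length in bp.
#' @param gc_target Genome-wide GC fraction.
#' @param delta_gc,delta_ta Leading-strand G and T excess probabilities.
#' @param ori,ter Replication origin/terminus positions (defaults 0 and
#'   `floor(length/2)`).
#' @param n_genes Number of genes (default fills ~55% of the chromosome
#'   with genes of mean length ~1250 bp).
#' @param gene_length Length-2 integer vector: min/max gene length.
#' @param leading_prob Probability a gene is oriented onto the leading
#'   strand.
#' @param cog_weights Named non-negative sampling weights over
#'   [COG_LETTERS] for the per-gene subcategory draw.
#' @param cog_leading_coupling Named per-letter additive shift applied to
#'   `leading_prob` for genes of that subcategory.
#' @param cog_annot_prob Probability a gene carries a COG annotation.
#' @param rsx_rate Probability an annotated gene is labelled with the
#'   excluded letter R instead (exercises the R/S/X filter downstream).
#' @param groups_per_letter COG ortholog groups simulated per letter.
#' @param pathway_rates Named per-pathway assignment probabilities over
#'   [KEGG_RR_PATHWAYS].
#' @param n_inversions Number of inversion events applied after placement.
#' @param inversion_length Length-2 vector: min/max inversion segment.
#' @return List of class `genome_sim_params`.
#' @export
genome_sim_params <- function(genome_id = "sim1", seed = 1L,
                              length = 5e5L, gc_target = 0.5,
                              delta_gc = 0.03, delta_ta = 0.02,
                              ori = 0L, ter = NULL,
                              n_genes = NULL,
                              gene_length = c(600L, 1900L),
                              leading_prob = 0.6,
                              cog_weights = NULL,
                              cog_leading_coupling = NULL,
                              cog_annot_prob = 0.8,
                              rsx_rate = 0.05,
                              groups_per_letter = 15L,
                              pathway_rates = NULL,
                              n_inversions = 0L,
                              inversion_length = c(2000L, 10000L)) {
  length <- as.integer(length)
  ter <- as.integer(ter %||% floor(length / 2))
  n_genes <- as.integer(n_genes %||% round(length * 0.55 / 1250))
  cog_weights <- cog_weights %||%
    stats::setNames(rep(1, base::length(COG_LETTERS)), COG_LETTERS)
  cog_leading_coupling <- cog_leading_coupling %||%
    stats::setNames(rep(0, base::length(COG_LETTERS)), COG_LETTERS)
  pathway_rates <- pathway_rates %||%
    stats::setNames(rep(0.008, base::length(KEGG_RR_PATHWAYS)), KEGG_RR_PATHWAYS)
  p <- structure(
    list(genome_id = genome_id, seed = as.integer(seed), length = length,
         gc_target = gc_target, delta_gc = delta_gc, delta_ta = delta_ta,
         ori = as.integer(ori), ter = ter, n_genes = n_genes,
         gene_length = as.integer(gene_length),
         leading_prob = leading_prob, cog_weights = cog_weights,
         cog_leading_coupling = cog_leading_coupling,
         cog_annot_prob = cog_annot_prob, rsx_rate = rsx_rate,
         groups_per_letter = as.integer(groups_per_letter),
         pathway_rates = pathway_rates,
         n_inversions = as.integer(n_inversions),
         inversion_length = as.integer(inversion_length)),
    class = "genome_sim_params"
  )
  validate_sim_params(p)
  p
}

base_probs <- function(p) {
  c(G = p$gc_target / 2 + p$delta_gc / 2,
    C = p$gc_target / 2 - p$delta_gc / 2,
    T = (1 - p$gc_target) / 2 + p$delta_ta / 2,
    A = (1 - p$gc_target) / 2 - p$delta_ta / 2)
}

validate_sim_params <- function(p) {
  probs <- base_probs(p)
  bad <- names(probs)[probs < 0 | probs > 1]
  if (base::length(bad) > 0L) {
    abort_bias(
      sprintf("gc_target/delta_gc/delta_ta imply an invalid base probability for %s (%s)",
              paste(bad, collapse = ", "),
              paste(sprintf("%.4f", probs[bad]), collapse = ", ")),
      "strandbias_error_params")
  }
  if (abs(sum(probs) - 1) > 1e-12) {
    abort_bias("base probabilities do not sum to 1", "strandbias_error_params")
  }
  check_oriter(p$ori, p$ter, p$length)
  if (p$leading_prob < 0 || p$leading_prob > 1) {
    abort_bias("leading_prob must be in [0, 1]", "strandbias_error_params")
  }
  invisible(p)
}

#' Simulate one circular genome with known strand bias
#'
#' Draws the composite leading strand site-wise from the base probabilities
#' implied by `gc_target`, `delta_gc` and `delta_ta`, complements it onto
#' the published strand over the second replichore, places non-overlapping
#' genes, assigns COG subcategories/ortholog groups and KEGG
#' replication-and-repair pathways, and optionally applies segment
#' inversions. Fully deterministic given `params$seed`.
#'
#' @param params A [genome_sim_params()] object.
#' @return List with elements `record` (a [genome_record()]), `cog` and
#'   `kegg` annotation tibbles, and `params`.
#' @examples
#' sim <- simulate_genome(genome_sim_params(length = 20000, n_genes = 8))
#' sim$record
#' @export
simulate_genome <- function(params) {
  validate_sim_params(params)
  withr::local_seed(params$seed)
  p <- params
  probs <- base_probs(p)
  bases <- names(probs)
  lead_idx <- sample.int(4L, p$length, replace = TRUE, prob = probs)
  lead_chars <- bases[lead_idx]
  # published strand: identity on arc1, complement on arc2
  comp <- c(G = "C", C = "G", T = "A", A = "T")
  map <- replichore_map(p$ori, p$ter, p$length)
  on1 <- in_arc1(seq_len(p$length) - 1L, map)
  pub <- lead_chars
  pub[!on1] <- comp[lead_chars[!on1]]
  sequence <- paste(pub, collapse = "")

  genes_and_annot <- place_genes(p, map)
  rec <- genome_record(p$genome_id, sequence, p$ori, p$ter,
                       genes_and_annot$genes)
  if (p$n_inversions > 0L) {
    inv <- apply_inversions(rec, p$n_inversions, p$inversion_length,
                            seed = p$seed + 1L)
    rec <- inv
    keep <- genes_and_annot$cog$gene_id %in% rec$genes$gene_id
    genes_and_annot$cog <- genes_and_annot$cog[keep, ]
    keep_k <- genes_and_annot$kegg$gene_id %in% rec$genes$gene_id
    genes_and_annot$kegg <- genes_and_annot$kegg[keep_k, ]
  }
  list(record = rec, cog = genes_and_annot$cog,
       kegg = genes_and_annot$kegg, params = p)
}

place_genes <- function(p, map) {
  n <- p$n_genes
  lens <- sample(seq(p$gene_length[1], p$gene_length[2]), n, replace = TRUE)
  if (sum(lens) > 0.9 * p$length) {
    abort_bias(sprintf("cannot pack %d genes (%d bp) into 90%% of a %d bp chromosome",
                       n, sum(lens), p$length), "strandbias_error_packing")
  }
  free <- p$length - sum(lens)
  cuts <- sort(stats::runif(n))
  gaps <- floor(diff(c(0, cuts)) * free)
  starts <- cumsum(gaps) + dplyr::lag(cumsum(lens), default = 0L)
  ends <- starts + lens
  mids <- gene_midpoint(starts, ends, p$length)
  gene_on1 <- in_arc1(mids, map)

  letters_pool <- c(COG_LETTERS, "R")
  w <- c(p$cog_weights[COG_LETTERS], R = 0)
  w <- w / sum(w)
  letter <- sample(letters_pool, n, replace = TRUE,
                   prob = c((1 - p$rsx_rate) * w[seq_along(COG_LETTERS)],
                            p$rsx_rate))
  shift <- ifelse(letter == "R", 0, p$cog_leading_coupling[letter])
  p_lead <- clamp(p$leading_prob + shift, 0.02, 0.98)
  is_leading <- stats::runif(n) < p_lead
  strand <- ifelse(gene_on1, ifelse(is_leading, "+", "-"),
                   ifelse(is_leading, "-", "+"))
  gene_id <- sprintf("%s_g%05d", p$genome_id, seq_len(n))
  genes <- tibble::tibble(gene_id = gene_id, start = as.integer(starts),
                          end = as.integer(ends), strand = strand)

  annotated <- stats::runif(n) < p$cog_annot_prob
  grp_no <- sample.int(p$groups_per_letter, n, replace = TRUE)
  cog <- tibble::tibble(
    genome_id = p$genome_id,
    gene_id = gene_id[annotated],
    cog_group_id = sprintf("COG_%s%02d", letter[annotated], grp_no[annotated]),
    subcategories = letter[annotated])

  rate_total <- sum(p$pathway_rates)
  has_pw <- stats::runif(n) < rate_total
  pw <- sample(KEGG_RR_PATHWAYS, sum(has_pw), replace = TRUE,
               prob = p$pathway_rates / rate_total)
  kegg <- tibble::tibble(genome_id = p$genome_id,
                         gene_id = gene_id[has_pw], pathway_id = pw)
  list(genes = genes, cog = cog, kegg = kegg)
}

#' Apply random segment inversions to a genome
#'
#' Each event reverse-complements a uniformly chosen segment in place,
#' flipping the strand and coordinates of genes fully inside it. Genes
#' straddling a breakpoint are deleted (with a message). Segments are
#' resampled (up to 50 tries, then the event is skipped with a warning) so
#' that they never contain the replication origin or terminus, keeping the
#' replichore map well defined.
#'
#' @param record A [genome_record()].
#' @param n Number of inversion events.
#' @param length_range Min/max segment length.
#' @param seed RNG seed.
#' @return A new [genome_record()] with the inverted sequence and updated
#'   gene table.
#' @export
apply_inversions <- function(record, n, length_range = c(2000L, 10000L),
                             seed = 1L) {
  if (n == 0L) return(record)
  withr::local_seed(seed)
  s <- record$sequence
  genes <- record$genes
  L <- record$length
  deleted <- 0L
  for (ev in seq_len(n)) {
    placed <- FALSE
    for (try in 1:50) {
      len <- sample(seq(length_range[1], length_range[2]), 1L)
      start <- sample.int(L - len, 1L) - 1L  # segment [start, start+len), no wrap
      end <- start + len
      contains <- function(pos) pos >= start && pos < end
      if (!contains(record$ori) && !contains(record$ter)) {
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      warning(sprintf("inversion event %d skipped: could not avoid ori/ter", ev))
      next
    }
    seg <- substr(s, start + 1L, end)
    s <- paste0(substr(s, 1L, start), revcomp(seg),
                substr(s, end + 1L, L))
    inside <- genes$start >= start & genes$end <= end
    straddle <- !inside & genes$start < end & genes$end > start
    if (any(straddle)) {
      deleted <- deleted + sum(straddle)
      genes <- genes[!straddle, ]
      inside <- genes$start >= start & genes$end <= end
    }
    new_start <- start + end - genes$end[inside]
    new_end <- start + end - genes$start[inside]
    genes$start[inside] <- new_start
    genes$end[inside] <- new_end
    genes$strand[inside] <- ifelse(genes$strand[inside] == "+", "-", "+")
  }
  if (deleted > 0L) {
    message(sprintf("apply_inversions: deleted %d gene(s) straddling breakpoints",
                    deleted))
  }
  genome_record(record$genome_id, s, record$ori, record$ter, genes)
}

#' Parameters for a simulated cohort
#'
#' Each genome draws a latent bias level `delta_sum` (split into
#' `delta_gc`/`delta_ta`); planted effects couple the standardised latent
#' level `z` to leading-strand gene density (+), GC content (-), genome
#' size (-), the obligate-intracellular flag (higher bias), and COG
#' subcategory usage (letters D, F, J, L, V up-weighted with `z`; A, C, I,
#' Q down-weighted), which in turn plants positive SCOG and negative WCOG
#' correlations. `effects = "null"` zeroes every coupling and holds
#' `delta_sum` constant while the other genome properties keep varying
#' independently, giving a calibration cohort with no real feature-score
#' relationships.
#'
#' @param n_genomes Number of genomes.
#' @param seed Integer RNG seed.
#' @param effects `"planted"` (default) or `"null"`.
#' @param mean_length Median genome length in bp.
#' @param delta_mean,delta_sdlog Median and log-sd of the latent
#'   `delta_sum` draw (planted mode).
#' @param delta_null Constant `delta_sum` used in null mode.
#' @param share_gc Fraction of `delta_sum` allocated to `delta_gc`.
#' @param obligate_rate Fraction of genomes flagged obligate-intracellular.
#' @param obligate_offset Additive `delta_sum` offset for flagged genomes.
#' @param beta_density,beta_gc,beta_size,cog_coupling Planted-effect
#'   coefficients (set to 0 in null mode).
#' @param n_inversions Per-genome inversion events.
#' @return List of class `cohort_sim_params`.
#' @export
cohort_sim_params <- function(n_genomes = 200L, seed = 1L,
                              effects = c("planted", "null"),
                              mean_length = 3e5,
                              delta_mean = 0.035, delta_sdlog = 0.5,
                              delta_null = 0.037,
                              share_gc = 0.675,
                              obligate_rate = 0.12,
                              obligate_offset = 0.018,
                              beta_density = 0.09,
                              beta_gc = 0.055,
                              beta_size = 0.30,
                              cog_coupling = 1.3,
                              n_inversions = 0L) {
  effects <- match.arg(effects)
  if (effects == "null") {
    obligate_offset <- 0
    beta_density <- 0
    beta_gc <- 0
    beta_size <- 0
    cog_coupling <- 0
  }
  structure(
    list(n_genomes = as.integer(n_genomes), seed = as.integer(seed),
         effects = effects, mean_length = mean_length,
         delta_mean = delta_mean, delta_sdlog = delta_sdlog,
         delta_null = delta_null, share_gc = share_gc,
         obligate_rate = obligate_rate, obligate_offset = obligate_offset,
         beta_density = beta_density, beta_gc = beta_gc,
         beta_size = beta_size, cog_coupling = cog_coupling,
         n_inversions = as.integer(n_inversions)),
    class = "cohort_sim_params"
  )
}

SIM_PHYLA <- c("Proteobacteria", "Firmicutes", "Actinobacteria",
               "Bacteroidetes", "Tenericutes", "Spirochaetes",
               "Chlamydiae", "Cyanobacteria", "Fusobacteria", "Thermotogae")
SIM_PHYLA_W <- c(0.35, 0.2, 0.12, 0.1, 0.06, 0.05, 0.04, 0.04, 0.02, 0.02)

COG_UP_LETTERS <- c("D", "F", "J", "L", "V")
COG_DOWN_LETTERS <- c("A", "C", "I", "Q")

#' Simulate a whole cohort of genomes
#'
#' Draws per-genome parameters under the cohort model of
#' [cohort_sim_params()], simulates every genome with [simulate_genome()],
#' and returns an in-memory cohort (optionally also written to disk with
#' [write_cohort()]). The ground-truth tibble records every drawn
#' parameter, so the expected value of each per-genome feature is known in
#' closed form.
#'
#' @param params A [cohort_sim_params()] object.
#' @param out_dir Optional directory; when given the cohort is written
#'   there via [write_cohort()].
#' @return List of class `bias_cohort`: `genomes` (list of
#'   [genome_record()]), `cog`, `kegg`, `metadata`, `truth` tibbles.
#' @export
simulate_cohort <- function(params = cohort_sim_params(), out_dir = NULL) {
  p <- params
  withr::local_seed(p$seed)
  n <- p$n_genomes
  gseeds <- sample.int(.Machine$integer.max - 2L, n)

  if (p$effects == "null") {
    delta_sum <- rep(p$delta_null, n)
    z <- rep(0, n)
  } else {
    z <- clamp(stats::rnorm(n), -2.5, 2.5)
    delta_sum <- clamp(p$delta_mean * exp(p$delta_sdlog * z), 0.004, 0.16)
  }
  obligate <- stats::runif(n) < p$obligate_rate
  delta_sum <- clamp(delta_sum + ifelse(obligate, p$obligate_offset, 0),
                     0.004, 0.18)
  if (p$effects != "null") {
    z <- (log(delta_sum) - log(p$delta_mean)) / p$delta_sdlog
  }
  rho <- clamp(0.60 + p$beta_density * z + 0.03 * stats::rnorm(n), 0.45, 0.95)
  gc <- clamp(0.50 - p$beta_gc * z + 0.04 * stats::rnorm(n), 0.25, 0.75)
  len <- as.integer(round(p$mean_length *
                            exp(-p$beta_size * z + 0.10 * stats::rnorm(n))))
  phylum <- sample(SIM_PHYLA, n, replace = TRUE, prob = SIM_PHYLA_W)
  s_value <- ifelse(stats::runif(n) < 0.8,
                    round(exp(stats::rnorm(n, 0, 0.6)), 4), NA_real_)
  gen_time <- ifelse(stats::runif(n) < 0.8,
                     round(exp(stats::rnorm(n, 1, 0.8)), 4), NA_real_)

  cog_w <- stats::setNames(rep(1, length(COG_LETTERS)), COG_LETTERS)
  genomes <- vector("list", n)
  cogs <- vector("list", n)
  keggs <- vector("list", n)
  ids <- sprintf("sim%04d", seq_len(n))
  for (i in seq_len(n)) {
    w <- cog_w
    w[COG_UP_LETTERS] <- w[COG_UP_LETTERS] * exp(p$cog_coupling * z[i])
    w[COG_DOWN_LETTERS] <- w[COG_DOWN_LETTERS] * exp(-p$cog_coupling * z[i])
    gp <- genome_sim_params(
      genome_id = ids[i], seed = gseeds[i], length = len[i],
      gc_target = gc[i],
      delta_gc = p$share_gc * delta_sum[i],
      delta_ta = (1 - p$share_gc) * delta_sum[i],
      leading_prob = rho[i], cog_weights = w,
      n_inversions = p$n_inversions)
    sim <- simulate_genome(gp)
    genomes[[i]] <- sim$record
    cogs[[i]] <- sim$cog
    keggs[[i]] <- sim$kegg
  }
  cohort <- structure(
    list(genomes = stats::setNames(genomes, ids),
         cog = dplyr::bind_rows(cogs),
         kegg = dplyr::bind_rows(keggs),
         metadata = tibble::tibble(
           genome_id = ids, phylum = phylum,
           obligate_intracellular = obligate,
           s_value = s_value, generation_time = gen_time),
         truth = tibble::tibble(
           genome_id = ids, seed = gseeds, length = len,
           delta_sum = delta_sum,
           delta_gc = p$share_gc * delta_sum,
           delta_ta = (1 - p$share_gc) * delta_sum,
           z = z, leading_prob = rho, gc_target = gc,
           obligate = obligate)),
    class = "bias_cohort"
  )
  if (!is.null(out_dir)) write_cohort(cohort, out_dir)
  cohort
}

#' @export
print.bias_cohort <- function(x, ...) {
  cat(sprintf("<bias_cohort> %d genomes, %d COG rows, %d KEGG rows\n",
              length(x$genomes), nrow(x$cog), nrow(x$kegg)))
  invisible(x)
}
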