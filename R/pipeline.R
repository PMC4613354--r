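# Orchestration: per-genome feature rows, cohort-level report, full runs.

#' Analysis configuration
#'
#' Collects every tunable of the pipeline with its default.
#'
#' @param rf_variant `"variance_over_mean"` (literal reading of the RF
#'   index) or `"sd_over_mean"` (coefficient-of-variation reading).
#' @param diff_level Level at which strong/weak count ratios are formed:
#'   `"group"` (COG ortholog groups, default) or `"subcategory"`.
#' @param scog_hi,wcog_lo SCOG/WCOG ratio thresholds (defaults 5, 0.2).
#' @param pseudocount Pseudocount for zero-denominator ratio groups
#'   (default 0 = exclude).
#' @param var_equal Pooled-variance Student t-test instead of Welch.
#' @param cutoff,strict_cutoff Significance conventions (0.05 and 1e-8).
#' @param pcr_features Explicit character vector of feature columns for
#'   the principal component regression; `NULL` (default) selects the
#'   features whose battery p-value passes `strict_cutoff`, falling back to
#'   `cutoff` and then to the core feature set when fewer than two qualify.
#' @return List of class `bias_config`.
#' @export
bias_config <- function(rf_variant = c("variance_over_mean", "sd_over_mean"),
                        diff_level = c("group", "subcategory"),
                        scog_hi = 5, wcog_lo = 0.2, pseudocount = 0,
                        var_equal = FALSE,
                        cutoff = 0.05, strict_cutoff = 1e-8,
                        pcr_features = NULL) {
  stopifnot(scog_hi > wcog_lo, wcog_lo > 0,
            cutoff > 0, cutoff < 1, strict_cutoff > 0, strict_cutoff < 1)
  structure(
    list(rf_variant = match.arg(rf_variant),
         diff_level = match.arg(diff_level),
         scog_hi = scog_hi, wcog_lo = wcog_lo, pseudocount = pseudocount,
         var_equal = var_equal, cutoff = cutoff,
         strict_cutoff = strict_cutoff, pcr_features = pcr_features),
    class = "bias_config"
  )
}

CORE_PCR_FEATURES <- c("genome_size", "gene_density_leading", "gc_content",
                       "gcRF", "taRF", "scog_fraction", "wcog_fraction")

#' Per-genome feature row
#'
#' Computes every genome-level statistic from one record: the
#' composition-bias score, genome size, GC content, leading-strand gene
#' density, the gcRF/taRF indices, the 23 COG subcategory percentages and
#' the ten replication-and-repair pathway proportions. Cohort-dependent
#' columns (SCOG/WCOG fractions) are added by [cohort_features()].
#' A genome whose sequence has no unambiguous bases yields `NA` statistics
#' with a warning rather than failing the run.
#'
#' @param record A [genome_record()].
#' @param cog,kegg Annotation tibbles for this genome (may be `NULL`).
#' @param rf_variant Passed to [rf_index()].
#' @return One-row tibble.
#' @export
genome_features <- function(record, cog = NULL, kegg = NULL,
                            rf_variant = "variance_over_mean") {
  map <- replichore_map(record$ori, record$ter, record$length)
  counts <- leading_strand_counts(record, map)
  degenerate <- with(counts, A + C + G + T) == 0
  if (degenerate) {
    warning(sprintf("genome %s has no unambiguous bases: NA feature row",
                    record$genome_id))
  }
  score <- if (degenerate) NA_real_ else
    composition_bias_score(counts, record$length)
  gc <- if (degenerate) NA_real_ else gc_content(counts)
  density <- tryCatch(gene_density_leading(record$genes, map),
                      strandbias_error_undefined = function(e) NA_real_)
  rf <- tryCatch({
    sk <- per_gene_skews(record, map)
    list(gc = rf_index(sk$gc_skew, rf_variant)$rf,
         ta = rf_index(sk$ta_skew, rf_variant)$rf)
  }, strandbias_error_undefined = function(e) list(gc = NA_real_,
                                                   ta = NA_real_))

  row <- tibble::tibble(
    genome_id = record$genome_id, score = score,
    genome_size = record$length, gc_content = gc,
    gene_density_leading = density, gcRF = rf$gc, taRF = rf$ta)

  pc <- tryCatch(pcog(cog %||% tibble::tibble(gene_id = character(),
                                              subcategories = character())),
                 strandbias_error_undefined = function(e) {
                   tibble::tibble(subcategory = COG_LETTERS, n = 0L,
                                  fraction = NA_real_)
                 })
  pcog_row <- stats::setNames(as.list(pc$fraction),
                              paste0("pCOG_", pc$subcategory))
  pw <- pathway_proportions(kegg %||% tibble::tibble(gene_id = character(),
                                                     pathway_id = character()),
                            n_genes = max(nrow(record$genes), 1L))
  pw_row <- stats::setNames(as.list(pw$fraction),
                            paste0("pathway_", pw$pathway_id))
  dplyr::bind_cols(row, tibble::as_tibble(pcog_row), tibble::as_tibble(pw_row))
}

#' Cohort feature table
#'
#' Runs [genome_features()] on every genome, splits the cohort into
#' strong/weak-biased halves by score, computes the COG group count ratios
#' and their subcategory averages (AVDT), selects SCOGs/WCOGs, adds the
#' per-genome SCOG/WCOG fractions, and joins the metadata columns. The
#' ratio table, AVDT table and selected sets are attached as attributes
#' `"diff_ratios"`, `"avdt"` and `"cog_sets"`.
#'
#' @param cohort A `bias_cohort` ([simulate_cohort()] or [load_cohort()]).
#' @param config A [bias_config()].
#' @return Feature tibble, one row per genome.
#' @export
cohort_features <- function(cohort, config = bias_config()) {
  rows <- purrr::map(cohort$genomes, function(rec) {
    genome_features(
      rec,
      cog = dplyr::filter(cohort$cog, .data$genome_id == rec$genome_id),
      kegg = dplyr::filter(cohort$kegg, .data$genome_id == rec$genome_id),
      rf_variant = config$rf_variant)
  })
  features <- dplyr::bind_rows(rows)

  usable <- dplyr::filter(features, !is.na(.data$score))
  split <- split_cohort(dplyr::select(usable, "genome_id", "score"))
  ratios <- diff_ratios(cohort$cog, split, diff_level = config$diff_level,
                        pseudocount = config$pseudocount)
  avdt_tbl <- suppressWarnings(avdt(ratios))
  sets <- select_scog_wcog(ratios, hi = config$scog_hi, lo = config$wcog_lo)
  props <- genome_group_proportions(cohort$cog, sets)
  features <- dplyr::left_join(features, props, by = "genome_id")
  features <- dplyr::mutate(
    features,
    scog_fraction = dplyr::if_else(
      .data$genome_id %in% unique(cohort$cog$genome_id),
      tidyr::replace_na(.data$scog_fraction, 0), .data$scog_fraction),
    wcog_fraction = dplyr::if_else(
      .data$genome_id %in% unique(cohort$cog$genome_id),
      tidyr::replace_na(.data$wcog_fraction, 0), .data$wcog_fraction))
  if (!is.null(cohort$metadata)) {
    features <- dplyr::left_join(features, cohort$metadata, by = "genome_id")
  }
  attr(features, "diff_ratios") <- ratios
  attr(features, "avdt") <- avdt_tbl
  attr(features, "cog_sets") <- sets
  features
}

#' Cohort-level statistical report
#'
#' Runs the Spearman battery of every feature against the score, the
#' obligate-intracellular group comparison (when the metadata column is
#' present with two usable groups), the per-phylum summaries, and the
#' principal component regression decomposition on the selected feature
#' set.
#'
#' @param features Feature table from [cohort_features()].
#' @param config A [bias_config()].
#' @return List of class `cohort_report`: `battery`, `group_test`,
#'   `phylum`, `pcr`, `pcr_features`, `avdt`, `config`.
#' @export
cohort_stats <- function(features, config = bias_config()) {
  features <- dplyr::filter(tibble::as_tibble(features), !is.na(.data$score))
  if (nrow(features) < 3L) {
    abort_bias("cohort statistics need at least three scored genomes",
               "strandbias_error_undefined")
  }
  battery <- suppressWarnings(correlation_battery(
    features, cutoff = config$cutoff, strict_cutoff = config$strict_cutoff))

  group_test <- NULL
  if ("obligate_intracellular" %in% names(features)) {
    g1 <- features$score[features$obligate_intracellular %in% TRUE]
    g2 <- features$score[features$obligate_intracellular %in% FALSE]
    if (length(g1) >= 2L && length(g2) >= 2L) {
      group_test <- group_t_test(g1, g2, var_equal = config$var_equal)
    }
  }
  phylum <- if ("phylum" %in% names(features)) {
    phylum_summaries(features)
  } else NULL

  pcr_feats <- select_pcr_features(features, battery, config)
  pcr <- pcr_decomposition(as.matrix(features[, pcr_feats]), features$score)

  structure(
    list(battery = battery, group_test = group_test, phylum = phylum,
         pcr = pcr, pcr_features = pcr_feats,
         avdt = attr(features, "avdt"), config = config),
    class = "cohort_report"
  )
}

# Feature columns for the PCR: those passing the strict battery cutoff,
# else the looser convention, else the core feature set; always restricted
# to complete, non-constant columns and excluding external metadata.
select_pcr_features <- function(features, battery, config) {
  if (!is.null(config$pcr_features)) return(config$pcr_features)
  internal <- setdiff(battery$feature,
                      c("s_value", "generation_time", "genome_id"))
  usable <- intersect(internal, names(features))
  usable <- usable[vapply(usable, function(col) {
    v <- features[[col]]
    !anyNA(v) && stats::sd(v) > 0
  }, logical(1))]
  b <- battery[battery$feature %in% usable, ]
  b <- b[order(b$p_value), ]
  max_k <- nrow(features) - 1L
  for (rule in list(b$feature[b$significant_strict],
                    b$feature[b$significant],
                    intersect(CORE_PCR_FEATURES, usable))) {
    if (length(rule) >= 2L) return(utils::head(rule, max_k))
  }
  abort_bias("fewer than two usable features for principal component regression",
             "strandbias_error_invalid")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("<cohort_report>\n")
  cat(sprintf("  battery: %d features, %d significant (p < %g), %d strict (p < %g)\n",
              nrow(x$battery), sum(x$battery$significant, na.rm = TRUE),
              x$config$cutoff,
              sum(x$battery$significant_strict, na.rm = TRUE),
              x$config$strict_cutoff))
  if (!is.null(x$group_test)) {
    cat(sprintf("  obligate-intracellular t-test: %.4f vs %.4f, p = %.4g\n",
                x$group_test$mean_group1, x$group_test$mean_group2,
                x$group_test$p_value))
  }
  cat(sprintf("  PCR on %d features: total R2 = %.4f\n",
              length(x$pcr_features), x$pcr$total_r2))
  invisible(x)
}

fmt_table <- function(tbl) {
  dplyr::mutate(tbl, dplyr::across(
    dplyr::where(is.numeric),
    ~ ifelse(is.na(.x), NA_character_, sprintf("%.6g", .x))))
}

#' Write a cohort report as deterministic TSV tables
#'
#' Emits `features.tsv`, `correlations.tsv`, `phylum_summary.tsv`,
#' `group_test.tsv`, `avdt.tsv` and `pcr.tsv` with fixed column order and
#' 6-significant-digit formatting, so identical inputs give byte-identical
#' outputs.
#'
#' @param report A [cohort_stats()] result.
#' @param features The feature table the report was computed from.
#' @param dir Output directory (created if needed).
#' @export
write_report <- function(report, features, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(tbl, name) {
    readr::write_tsv(fmt_table(tbl), file.path(dir, name), na = ".")
  }
  w(dplyr::arrange(tibble::as_tibble(features), .data$genome_id),
    "features.tsv")
  w(tibble::as_tibble(report$battery), "correlations.tsv")
  if (!is.null(report$phylum)) w(report$phylum, "phylum_summary.tsv")
  if (!is.null(report$group_test)) w(report$group_test, "group_test.tsv")
  if (!is.null(report$avdt)) w(report$avdt, "avdt.tsv")
  w(tidy(report$pcr), "pcr.tsv")
  w(glance(report$pcr), "pcr_summary.tsv")
  invisible(dir)
}

#' Run the full pipeline: simulate, features, cohort statistics
#'
#' Simulates a cohort, writes it to `<out_dir>/cohort`, computes the
#' feature table and the statistical report, and writes all report tables
#' to `<out_dir>/report`. Deterministic: the same parameters, config and
#' seed give byte-identical outputs.
#'
#' @param out_dir Output directory.
#' @param sim_params A [cohort_sim_params()].
#' @param config A [bias_config()].
#' @return Invisibly, a list with `cohort`, `features`, `report`.
#' @export
run_all <- function(out_dir, sim_params = cohort_sim_params(),
                    config = bias_config()) {
  cohort <- simulate_cohort(sim_params,
                            out_dir = file.path(out_dir, "cohort"))
  features <- cohort_features(cohort, config)
  report <- cohort_stats(features, config)
  write_report(report, features, file.path(out_dir, "report"))
  invisible(list(cohort = cohort, features = features, report = report))
}
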