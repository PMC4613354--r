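# COG / KEGG functional-category statistics.

#' COG subcategory letters retained in the analysis
#'
#' The 23 one-letter COG functional subcategories, i.e. A..Z with the
#' uninformative letters R ("general function prediction"), S ("function
#' unknown") and X excluded before any counting.
#' @export
COG_LETTERS <- setdiff(LETTERS, c("R", "S", "X"))

#' The ten KEGG replication-and-repair pathways
#'
#' DNA replication, DNA replication proteins, chromosome and associated
#' proteins, DNA repair and recombination proteins, base excision repair,
#' nucleotide excision repair, mismatch repair, homologous recombination,
#' non-homologous end-joining, and the Fanconi anemia pathway.
#' @export
KEGG_RR_PATHWAYS <- c("ko03030", "ko03032", "ko03036", "ko03400", "ko03410",
                      "ko03420", "ko03430", "ko03440", "ko03450", "ko03460")

# Split "KL"-style multi-letter subcategory strings into one row per letter.
expand_letters <- function(tbl, col = "subcategories") {
  tbl <- dplyr::mutate(tbl, .letter = stringr::str_split(.data[[col]], ""))
  tidyr::unnest(tbl, ".letter")
}

#' COG functional subcategory percentages (pCOG)
#'
#' Counts every (gene, subcategory letter) assignment after dropping the
#' letters R, S and X, and normalises by the total surviving count, giving
#' the percentage of each COG functional subcategory in one genome. A gene
#' annotated with a multi-letter subcategory string (e.g. "KL") contributes
#' one count to each letter.
#'
#' @param assignments Tibble with columns `gene_id` and `subcategories`
#'   (string of one-letter codes) for one genome.
#' @return Tibble with one row per retained letter (all 23, in alphabetical
#'   order): `subcategory`, `n`, `fraction`. Fractions sum to 1.
#' @examples
#' pcog(tibble::tibble(gene_id = c("a", "b"), subcategories = c("J", "KL")))
#' @export
pcog <- function(assignments) {
  letters_tbl <- expand_letters(tibble::as_tibble(assignments))
  letters_tbl <- dplyr::filter(letters_tbl, .data$.letter %in% COG_LETTERS)
  if (nrow(letters_tbl) == 0L) {
    abort_bias("no COG assignments survive the R/S/X filter: pCOG undefined",
               "strandbias_error_undefined")
  }
  counts <- dplyr::count(letters_tbl, subcategory = .data$.letter)
  out <- dplyr::left_join(tibble::tibble(subcategory = COG_LETTERS), counts,
                          by = "subcategory")
  out <- dplyr::mutate(out, n = tidyr::replace_na(.data$n, 0L),
                       fraction = .data$n / sum(.data$n))
  out
}

#' Split a cohort into strong- and weak-biased genome groups
#'
#' The strong-biased group (SBG) is the top `floor(N/2)` genomes by
#' composition-bias score (for a 1111-genome cohort, the top 555); the rest
#' form the weak-biased group (WBG). Ties are broken by `genome_id` in
#' lexicographic order so the split is deterministic.
#'
#' @param scores Tibble with columns `genome_id` and `score`.
#' @return The input with an added `bias_group` column (`"SBG"`/`"WBG"`).
#' @export
split_cohort <- function(scores) {
  scores <- tibble::as_tibble(scores)
  if (nrow(scores) < 2L) {
    abort_bias("cohort split needs at least two genomes",
               "strandbias_error_undefined")
  }
  ord <- order(-scores$score, scores$genome_id)
  n_sbg <- floor(nrow(scores) / 2)
  grp <- character(nrow(scores))
  grp[ord] <- rep(c("SBG", "WBG"), c(n_sbg, nrow(scores) - n_sbg))
  dplyr::mutate(scores, bias_group = grp)
}

#' Strong/weak-group gene-count ratios per COG ortholog group
#'
#' For each COG ortholog group, the ratio of its gene count summed over the
#' strong-biased genomes to its count over the weak-biased genomes
#' (Diff_SBG/WBG). Groups absent from the weak-biased group are excluded
#' under the default policy (ratio undefined) or retained with a
#' pseudocount added to both counts.
#'
#' @param cog Cohort COG table: `genome_id`, `gene_id`, `cog_group_id`,
#'   `subcategories`.
#' @param split Output of [split_cohort()].
#' @param diff_level `"group"` (default: ratios per COG ortholog group) or
#'   `"subcategory"` (the literal per-letter reading).
#' @param pseudocount Non-negative count added to both numerator and
#'   denominator; 0 (default) excludes zero-denominator groups with a
#'   warning.
#' @return Tibble: `cog_group_id` (or `subcategory`), `subcategories`,
#'   `n_sbg`, `n_wbg`, `ratio`.
#' @export
diff_ratios <- function(cog, split, diff_level = c("group", "subcategory"),
                        pseudocount = 0) {
  diff_level <- match.arg(diff_level)
  cog <- dplyr::inner_join(tibble::as_tibble(cog),
                           dplyr::select(split, "genome_id", "bias_group"),
                           by = "genome_id")
  if (diff_level == "group") {
    counts <- dplyr::count(cog, .data$cog_group_id, .data$subcategories,
                           .data$bias_group)
    counts <- tidyr::pivot_wider(counts, names_from = "bias_group",
                                 values_from = "n", values_fill = 0L)
  } else {
    letters_tbl <- expand_letters(cog)
    letters_tbl <- dplyr::filter(letters_tbl, .data$.letter %in% COG_LETTERS)
    counts <- dplyr::count(letters_tbl, cog_group_id = .data$.letter,
                           .data$bias_group)
    counts <- dplyr::mutate(counts, subcategories = .data$cog_group_id)
    counts <- tidyr::pivot_wider(counts, names_from = "bias_group",
                                 values_from = "n", values_fill = 0L)
  }
  for (col in c("SBG", "WBG")) {
    if (!col %in% names(counts)) counts[[col]] <- 0L
  }
  out <- dplyr::transmute(counts,
                          cog_group_id = .data$cog_group_id,
                          subcategories = .data$subcategories,
                          n_sbg = .data$SBG, n_wbg = .data$WBG)
  if (pseudocount > 0) {
    out <- dplyr::mutate(out, ratio = (.data$n_sbg + pseudocount) /
                           (.data$n_wbg + pseudocount))
  } else {
    drop <- out$n_wbg == 0L
    if (any(drop)) {
      warning(sprintf("excluding %d COG group(s) absent from the weak-biased group",
                      sum(drop)))
      out <- out[!drop, ]
    }
    out <- dplyr::mutate(out, ratio = .data$n_sbg / .data$n_wbg)
  }
  dplyr::arrange(out, .data$cog_group_id)
}

#' Average value of discrepant times (AVDT) per COG subcategory
#'
#' The AVDT of a functional subcategory is the arithmetic mean of the
#' strong/weak-group count ratios over the ortholog groups mapped to that
#' subcategory. A multi-letter group contributes to each of its letters.
#'
#' @param ratios Output of [diff_ratios()].
#' @return Tibble: `subcategory`, `avdt`, `n_groups`, sorted by descending
#'   `avdt`. Subcategories with no contributing group are omitted with a
#'   warning.
#' @export
avdt <- function(ratios) {
  letters_tbl <- expand_letters(tibble::as_tibble(ratios))
  letters_tbl <- dplyr::filter(letters_tbl, .data$.letter %in% COG_LETTERS)
  out <- dplyr::summarise(
    dplyr::group_by(letters_tbl, subcategory = .data$.letter),
    avdt = mean(.data$ratio), n_groups = dplyr::n(), .groups = "drop")
  missing <- setdiff(COG_LETTERS, out$subcategory)
  if (length(missing) > 0L) {
    warning(sprintf("no contributing COG groups for subcategories: %s",
                    paste(missing, collapse = ", ")))
  }
  dplyr::arrange(out, dplyr::desc(.data$avdt), .data$subcategory)
}

#' Select strong- and weak-biased COG groups (SCOGs / WCOGs)
#'
#' Groups whose strong/weak count ratio exceeds `hi` are the strong-biased
#' COG groups; those below `lo` are the weak-biased COG groups.
#'
#' @param ratios Output of [diff_ratios()].
#' @param hi,lo Ratio thresholds, defaults 5 and 0.2.
#' @return List of class `cog_group_sets` with character vectors `scog_ids`
#'   and `wcog_ids` (disjoint).
#' @export
select_scog_wcog <- function(ratios, hi = 5, lo = 0.2) {
  stopifnot(hi > lo, lo > 0)
  structure(
    list(scog_ids = sort(ratios$cog_group_id[ratios$ratio > hi]),
         wcog_ids = sort(ratios$cog_group_id[ratios$ratio < lo])),
    class = "cog_group_sets"
  )
}

#' Per-genome SCOG and WCOG proportions
#'
#' Fraction of a genome's COG-annotated genes whose ortholog group belongs
#' to the strong-biased (resp. weak-biased) group set. A gene annotated
#' with several groups counts as SCOG/WCOG membership if any of them is in
#' the set; the denominator is the number of COG-annotated genes.
#'
#' @param cog Cohort COG table (`genome_id`, `gene_id`, `cog_group_id`, ...).
#' @param sets A [select_scog_wcog()] result.
#' @return Tibble: `genome_id`, `scog_fraction`, `wcog_fraction`.
#' @export
genome_group_proportions <- function(cog, sets) {
  cog <- tibble::as_tibble(cog)
  per_gene <- dplyr::summarise(
    dplyr::group_by(cog, .data$genome_id, .data$gene_id),
    in_scog = any(.data$cog_group_id %in% sets$scog_ids),
    in_wcog = any(.data$cog_group_id %in% sets$wcog_ids),
    .groups = "drop")
  dplyr::summarise(dplyr::group_by(per_gene, .data$genome_id),
                   scog_fraction = mean(.data$in_scog),
                   wcog_fraction = mean(.data$in_wcog),
                   .groups = "drop")
}

#' Replication-and-repair pathway gene proportions
#'
#' For one genome, the fraction of its genes assigned to each of the ten
#' KEGG replication-and-repair pathways. Pathways with no genes are
#' reported as 0.
#'
#' @param kegg Tibble with columns `gene_id`, `pathway_id` for one genome.
#' @param n_genes Total number of annotated genes in the genome (the
#'   denominator).
#' @return Tibble: `pathway_id`, `n`, `fraction`, one row per pathway in
#'   [KEGG_RR_PATHWAYS] order.
#' @export
pathway_proportions <- function(kegg, n_genes) {
  if (n_genes <= 0) {
    abort_bias("pathway proportions undefined: genome has no genes",
               "strandbias_error_undefined")
  }
  kegg <- tibble::as_tibble(kegg)
  unknown <- setdiff(unique(kegg$pathway_id), KEGG_RR_PATHWAYS)
  if (length(unknown) > 0L) {
    abort_bias(sprintf("unknown KEGG pathway id(s): %s",
                       paste(unknown, collapse = ", ")),
               "strandbias_error_parse")
  }
  counts <- dplyr::count(kegg, pathway_id = .data$pathway_id)
  out <- dplyr::left_join(tibble::tibble(pathway_id = KEGG_RR_PATHWAYS),
                          counts, by = "pathway_id")
  dplyr::mutate(out, n = tidyr::replace_na(.data$n, 0L),
                fraction = .data$n / n_genes)
}
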