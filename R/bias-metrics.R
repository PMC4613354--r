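#' Composition-bias score of a genome
#'
#' The strand composition bias of a whole genome is
#' \deqn{Score = (|G - C| + |T - A|) / L}
#' where G, C, T, A are base counts on the composite leading strand and L is
#' the chromosome length. By base-pairing complementarity the lagging strand
#' gives the same value. Ambiguous bases are excluded from the counts but
#' the denominator stays the full chromosome length.
#'
#' @param counts One-row tibble (or named list) of leading-strand base
#'   counts as returned by [leading_strand_counts()].
#' @param length Chromosome length in bp.
#' @return Score in `[0, 1]`.
#' @examples
#' composition_bias_score(list(G = 30, C = 20, T = 25, A = 25), 100)
#' @export
composition_bias_score <- function(counts, length) {
  if (length <= 0) {
    abort_bias("composition-bias score undefined for length <= 0",
               "strandbias_error_undefined")
  }
  (abs(counts$G - counts$C) + abs(counts$T - counts$A)) / length
}

#' GC content
#'
#' Fraction of unambiguous bases that are G or C.
#'
#' @inheritParams composition_bias_score
#' @return Fraction in `[0, 1]`.
#' @export
gc_content <- function(counts) {
  total <- counts$A + counts$C + counts$G + counts$T
  if (total <= 0) {
    abort_bias("GC content undefined: no unambiguous bases",
               "strandbias_error_undefined")
  }
  (counts$G + counts$C) / total
}

#' Per-gene GC and TA skews of leading-strand genes
#'
#' For every leading-strand gene computes its coding-orientation skews
#' \eqn{(G_i - C_i)/L_i} and \eqn{(T_i - A_i)/L_i}, where counts are taken
#' on the gene's own reading (for leading genes this equals its
#' leading-strand reading) and \eqn{L_i} is the gene length. Lagging genes
#' are excluded.
#'
#' @param record A [genome_record()] with annotations.
#' @param map Optional [replichore_map()]; defaults to the record's ori/ter.
#' @return Tibble with one row per leading-strand gene: `gene_id`, `length`,
#'   `gc_skew`, `ta_skew`.
#' @export
per_gene_skews <- function(record, map = NULL) {
  map <- map %||% replichore_map(record$ori, record$ter, record$length)
  genes <- classify_genes(record$genes, map)
  lead <- dplyr::filter(genes, .data$replichore == "leading")
  if (nrow(lead) == 0L) {
    abort_bias("no leading-strand genes: per-gene skews undefined",
               "strandbias_error_undefined")
  }
  seqs <- extract_gene_sequences(record$sequence, lead$start, lead$end,
                                 record$length)
  gp <- stringr::str_count(seqs, stringr::fixed("G"))
  cp <- stringr::str_count(seqs, stringr::fixed("C"))
  tp <- stringr::str_count(seqs, stringr::fixed("T"))
  ap <- stringr::str_count(seqs, stringr::fixed("A"))
  # a '-' strand gene reads the complement: G<->C and T<->A swap
  g <- ifelse(lead$strand == "+", gp, cp)
  c_ <- ifelse(lead$strand == "+", cp, gp)
  t_ <- ifelse(lead$strand == "+", tp, ap)
  a <- ifelse(lead$strand == "+", ap, tp)
  len <- lead$end - lead$start
  out <- tibble::tibble(gene_id = lead$gene_id, length = len,
                        gc_skew = (g - c_) / len, ta_skew = (t_ - a) / len)
  zero <- out$length == 0L
  if (any(zero)) {
    warning(sprintf("excluding %d zero-length genes from skew vectors",
                    sum(zero)))
    out <- out[!zero, ]
  }
  out
}

# Published-strand substrings for (possibly origin-wrapping) genes.
extract_gene_sequences <- function(sequence, start, end, len) {
  purrr::map2_chr(start, end, function(s, e) {
    if (e <= len) substr(sequence, s + 1L, e)
    else paste0(substr(sequence, s + 1L, len), substr(sequence, 1L, e - len))
  })
}

#' Recombination-counteraction index (gcRF / taRF)
#'
#' Dispersion-over-mean of a vector of per-gene skews: the sample variance
#' of the skews divided by their mean (`rf_variant = "variance_over_mean"`,
#' the default) or the sample standard deviation divided by the mean
#' (`"sd_over_mean"`, the coefficient-of-variation reading). Frequent
#' rearrangement scatters per-gene skews around a reduced mean, so higher
#' values indicate more recombination counteracting the replication bias.
#'
#' @param skews Numeric vector of per-gene skews (length >= 2).
#' @param rf_variant `"variance_over_mean"` (default) or `"sd_over_mean"`.
#' @return One-row tibble with `mean_skew`, `rf`, `n`. When the mean skew is
#'   exactly zero `rf` is `NA` (never infinite).
#' @examples
#' rf_index(c(0.2, 0))
#' @export
rf_index <- function(skews, rf_variant = c("variance_over_mean", "sd_over_mean")) {
  rf_variant <- match.arg(rf_variant)
  n <- length(skews)
  if (n < 2L) {
    abort_bias("RF index needs at least two per-gene skews",
               "strandbias_error_undefined")
  }
  m <- mean(skews)
  disp <- stats::var(skews)
  if (rf_variant == "sd_over_mean") disp <- sqrt(disp)
  rf <- if (m == 0) NA_real_ else disp / m
  tibble::tibble(mean_skew = m, rf = rf, n = n)
}
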