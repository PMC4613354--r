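#' Construct a genome record
#'
#' Bundles one circular bacterial chromosome with its replication origin and
#' terminus coordinates and (optionally) its gene annotations. All
#' coordinates are 0-based half-open; `ori`/`ter` are single breakpoint
#' positions in `[0, length)`.
#'
#' @param genome_id Single string identifying the chromosome.
#' @param sequence Single uppercase string over the IUPAC alphabet.
#' @param ori,ter Integer replication origin / terminus positions (0-based).
#' @param genes Tibble of gene annotations with columns `gene_id`, `start`,
#'   `end` (0-based half-open; `end` may exceed the chromosome length for a
#'   gene wrapping the coordinate origin) and `strand` (`"+"` or `"-"`).
#'   May be `NULL` for an annotation-free record.
#' @return An object of class `genome_record`: a list with fields
#'   `genome_id`, `sequence`, `length`, `ori`, `ter`, `genes`.
#' @examples
#' rec <- genome_record("g1", "ACGTACGTAC", ori = 0, ter = 5)
#' rec$length
#' @export
genome_record <- function(genome_id, sequence, ori, ter, genes = NULL) {
  stopifnot(is.character(genome_id), length(genome_id) == 1L,
            is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  validate_sequence(sequence, what = paste0("sequence of ", genome_id))
  len <- nchar(sequence)
  check_oriter(ori, ter, len)
  if (is.null(genes)) {
    genes <- empty_gene_table()
  } else {
    genes <- tibble::as_tibble(genes)
    stopifnot(all(c("gene_id", "start", "end", "strand") %in% names(genes)))
    if (any(genes$end <= genes$start)) {
      abort_bias("gene annotations must satisfy start < end (wrap genes use end > length)",
                 "strandbias_error_coords")
    }
    if (!all(genes$strand %in% c("+", "-"))) {
      abort_bias("gene strand must be '+' or '-'", "strandbias_error_parse")
    }
  }
  structure(
    list(genome_id = genome_id, sequence = sequence, length = len,
         ori = as.integer(ori), ter = as.integer(ter), genes = genes),
    class = "genome_record"
  )
}

empty_gene_table <- function() {
  tibble::tibble(gene_id = character(), start = integer(),
                 end = integer(), strand = character())
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s: %d bp, ori=%d, ter=%d, %d genes\n",
              x$genome_id, x$length, x$ori, x$ter, nrow(x$genes)))
  invisible(x)
}

check_oriter <- function(ori, ter, len) {
  if (ori < 0 || ori >= len || ter < 0 || ter >= len) {
    abort_bias(sprintf("ori/ter out of range for length %d (ori=%s, ter=%s)",
                       len, ori, ter), "strandbias_error_coords")
  }
  if (ori == ter) {
    abort_bias("ori and ter must differ", "strandbias_error_coords")
  }
  invisible(TRUE)
}

#' Partition a circular chromosome into its two replichores
#'
#' The replication fork leaving the origin clockwise (in the direction of
#' increasing published-strand coordinates) synthesises the published strand
#' continuously over arc 1 = `[ori, ter)`, so there the published strand is
#' the leading strand. On arc 2 = `[ter, ori)` the leading strand is the
#' reverse complement of the published strand. Both arcs are circular
#' 0-based half-open intervals modulo `length`.
#'
#' @param ori,ter Breakpoint positions in `[0, length)`, `ori != ter`.
#' @param length Chromosome length in bp.
#' @return An object of class `replichore_map` with fields `ori`, `ter`,
#'   `length`, and the two arc lengths.
#' @examples
#' m <- replichore_map(0, 500, 1000)
#' in_arc1(c(0, 499, 500, 999), m)
#' @export
replichore_map <- function(ori, ter, length) {
  check_oriter(ori, ter, length)
  ori <- as.integer(ori); ter <- as.integer(ter); length <- as.integer(length)
  structure(
    list(ori = ori, ter = ter, length = length,
         arc1_len = (ter - ori) %% length,
         arc2_len = (ori - ter) %% length),
    class = "replichore_map"
  )
}

#' @export
print.replichore_map <- function(x, ...) {
  cat(sprintf("<replichore_map> L=%d, arc1=[%d,%d) (%d bp, + leading), arc2=[%d,%d) (%d bp, - leading)\n",
              x$length, x$ori, x$ter, x$arc1_len, x$ter, x$ori, x$arc2_len))
  invisible(x)
}

#' Which positions fall on the first replichore?
#'
#' @param pos Integer vector of 0-based positions (taken modulo the
#'   chromosome length).
#' @param map A [replichore_map()].
#' @return Logical vector: `TRUE` where the position lies in arc 1
#'   (`[ori, ter)`), `FALSE` for arc 2.
#' @export
in_arc1 <- function(pos, map) {
  ((pos - map$ori) %% map$length) < map$arc1_len
}

#' Classify genes as leading- or lagging-strand
#'
#' A gene transcribed co-directionally with the replication fork is a
#' leading-strand gene: a `+`-strand gene whose midpoint lies on arc 1, or a
#' `-`-strand gene whose midpoint lies on arc 2. Midpoints are computed
#' modulo the chromosome length, so genes wrapping the coordinate origin
#' (annotated with `end > length`) are handled like any other gene.
#'
#' @param genes Tibble with columns `gene_id`, `start`, `end`, `strand`.
#' @param map A [replichore_map()].
#' @return The input tibble with an added `replichore` column
#'   (`"leading"`/`"lagging"`).
#' @export
classify_genes <- function(genes, map) {
  genes <- tibble::as_tibble(genes)
  mid <- gene_midpoint(genes$start, genes$end, map$length)
  on1 <- in_arc1(mid, map)
  leading <- (genes$strand == "+" & on1) | (genes$strand == "-" & !on1)
  dplyr::mutate(genes,
                replichore = dplyr::if_else(leading, "leading", "lagging"))
}

gene_midpoint <- function(start, end, len) {
  floor((start + end) / 2) %% len
}

#' Base counts of the composite leading strand
#'
#' Concatenates the published-strand bases over arc 1 with the complemented
#' published-strand bases over arc 2 (the leading strand of the second
#' replichore) and counts A/C/G/T. Ambiguity codes are excluded from the
#' four counts and tallied in `n_ambiguous`.
#'
#' @param record A [genome_record()].
#' @param map Optional [replichore_map()]; defaults to the record's own
#'   ori/ter.
#' @return One-row tibble with columns `A`, `C`, `G`, `T`, `n_ambiguous`.
#' @examples
#' rec <- genome_record("g1", "GGGG", ori = 0, ter = 2)
#' leading_strand_counts(rec)
#' @export
leading_strand_counts <- function(record, map = NULL) {
  map <- map %||% replichore_map(record$ori, record$ter, record$length)
  stopifnot(map$length == record$length)
  s1 <- arc_substring(record$sequence, map$ori, map$ter, record$length)
  s2 <- arc_substring(record$sequence, map$ter, map$ori, record$length)
  counts <- count_acgt(s1) + complement_counts(count_acgt(s2))
  tibble::tibble(A = counts[["A"]], C = counts[["C"]],
                 G = counts[["G"]], T = counts[["T"]],
                 n_ambiguous = record$length - sum(counts))
}

#' Leading-strand gene density
#'
#' Fraction of genes classified as leading-strand, the gene orientation bias
#' statistic correlated with the composition-bias score across cohorts.
#'
#' @inheritParams classify_genes
#' @return A single number in `[0, 1]`.
#' @export
gene_density_leading <- function(genes, map) {
  if (nrow(genes) == 0L) {
    abort_bias("gene density is undefined for an empty gene list",
               "strandbias_error_undefined")
  }
  cls <- classify_genes(genes, map)
  mean(cls$replichore == "leading")
}
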