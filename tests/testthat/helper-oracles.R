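# Independent brute-force oracles, deliberately naive: they walk positions
# one by one and never share code with the package implementation.

# Positions reached by walking from ori towards increasing coordinates
# (the fork direction of arc 1) until ter is hit.
brute_arc1_positions <- function(ori, ter, len) {
  pos <- integer(0)
  p <- ori
  while (p != ter) {
    pos <- c(pos, p)
    p <- (p + 1) %% len
  }
  pos
}

COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

# Per-position classification + complementation, then a plain tally.
brute_leading_counts <- function(sequence, ori, ter) {
  len <- nchar(sequence)
  chars <- strsplit(sequence, "")[[1]]
  in1 <- logical(len)
  in1[brute_arc1_positions(ori, ter, len) + 1L] <- TRUE
  counts <- c(A = 0L, C = 0L, G = 0L, T = 0L, n_ambiguous = 0L)
  for (p in seq_len(len)) {
    base <- chars[p]
    if (!in1[p]) base <- unname(COMP[base])
    if (base %in% c("A", "C", "G", "T")) {
      counts[base] <- counts[base] + 1L
    } else {
      counts["n_ambiguous"] <- counts["n_ambiguous"] + 1L
    }
  }
  counts
}

# Spearman rho as rank-then-Pearson, ties by average ranks.
brute_spearman_rho <- function(x, y) {
  stats::cor(rank(x), rank(y))
}

# Random chromosome with genes, built with base R only.
random_test_genome <- function(seed, len_range = c(200L, 2000L),
                               n_genes = NULL, with_n = FALSE) {
  set.seed(seed)
  len <- sample(len_range[1]:len_range[2], 1)
  alphabet <- if (with_n) c("A", "C", "G", "T", "N") else c("A", "C", "G", "T")
  sequence <- paste(sample(alphabet, len, replace = TRUE,
                           prob = if (with_n) c(rep(0.24, 4), 0.04) else NULL),
                    collapse = "")
  ot <- sample(0:(len - 1), 2)
  n_genes <- if (is.null(n_genes)) sample(3:12, 1) else n_genes
  starts <- sort(sample(0:(len - 2), n_genes))
  ends <- pmin(starts + sample(10:60, n_genes, replace = TRUE), len)
  keep <- ends > starts
  genes <- tibble::tibble(
    gene_id = sprintf("g%03d", seq_len(sum(keep))),
    start = starts[keep], end = ends[keep],
    strand = sample(c("+", "-"), sum(keep), replace = TRUE))
  genome_record(paste0("rand", seed), sequence, ot[1], ot[2], genes)
}

# Reverse-complement a whole genome record, swapping ori/ter and remapping
# gene coordinates, as an independent transformation for symmetry checks.
revcomp_genome <- function(record) {
  chars <- strsplit(record$sequence, "")[[1]]
  rc <- paste(rev(unname(COMP[chars])), collapse = "")
  len <- record$length
  genes <- record$genes
  new_genes <- tibble::tibble(
    gene_id = genes$gene_id,
    start = len - genes$end,
    end = len - genes$start,
    strand = ifelse(genes$strand == "+", "-", "+"))
  genome_record(record$genome_id, rc,
                ori = (len - record$ori) %% len,
                ter = (len - record$ter) %% len,
                genes = new_genes)
}
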