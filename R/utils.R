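# Internal helpers shared across modules.

# IUPAC nucleotide codes accepted in input sequences; only A/C/G/T are
# counted, everything else lands in n_ambiguous.
IUPAC_CHARS <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N")

abort_bias <- function(msg, class) {
  rlang::abort(msg, class = c(class, "strandbias_error"))
}

#' @noRd
validate_sequence <- function(sequence, what = "sequence") {
  bad <- stringr::str_locate(sequence,
                             paste0("[^", paste(IUPAC_CHARS, collapse = ""), "]"))[1, 1]
  if (!is.na(bad)) {
    abort_bias(
      sprintf("illegal character '%s' in %s at position %d",
              substr(sequence, bad, bad), what, bad),
      "strandbias_error_parse"
    )
  }
  invisible(sequence)
}

# Reverse complement of an unambiguous/IUPAC DNA string.
revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# Counts of A/C/G/T in a string (ambiguity codes excluded from the counts).
count_acgt <- function(s) {
  c(A = stringr::str_count(s, stringr::fixed("A")),
    C = stringr::str_count(s, stringr::fixed("C")),
    G = stringr::str_count(s, stringr::fixed("G")),
    T = stringr::str_count(s, stringr::fixed("T")))
}

# Substring of a circular sequence over the 0-based half-open arc
# [from, to) taken modulo the sequence length; to == from yields the whole
# circle only when explicitly allowed upstream (never used that way here).
arc_substring <- function(s, from, to, len) {
  from <- from %% len
  to <- to %% len
  if (from < to) {
    substr(s, from + 1L, to)
  } else {
    paste0(substr(s, from + 1L, len), substr(s, 1L, to))
  }
}

# Swap counts to their complement (A<->T, C<->G).
complement_counts <- function(counts) {
  c(A = counts[["T"]], C = counts[["G"]], G = counts[["C"]], T = counts[["A"]])
}

`%||%` <- function(x, y) if (is.null(x)) y else x
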