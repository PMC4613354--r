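# Readers and writers for every external format the pipeline touches.
# TSV dialect throughout: tab-separated, header row required, UTF-8,
# "." or empty = missing, no quoting.

read_tsv_strict <- function(path, col_types) {
  if (!file.exists(path)) {
    abort_bias(paste0("file not found: ", path), "strandbias_error_io")
  }
  readr::read_tsv(path, col_types = col_types, na = c("", "."),
                  progress = FALSE)
}

require_columns <- function(tbl, cols, path) {
  missing <- setdiff(cols, names(tbl))
  if (length(missing) > 0L) {
    abort_bias(sprintf("%s: missing required column(s): %s",
                       path, paste(missing, collapse = ", ")),
               "strandbias_error_parse")
  }
  invisible(tbl)
}

#' Read a single-record FASTA file
#'
#' @param path Path to a FASTA file holding exactly one chromosome.
#' @return List with `genome_id` (first token of the header) and
#'   `sequence` (uppercased). Characters outside the IUPAC alphabet raise
#'   an error naming the offending position.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) != 1L) {
    abort_bias(sprintf("%s: expected exactly one FASTA record, found %d",
                       path, length(set)), "strandbias_error_parse")
  }
  sequence <- toupper(as.character(set[[1L]]))
  validate_sequence(sequence, what = path)
  list(genome_id = strsplit(names(set), "\\s+")[[1L]][1L],
       sequence = sequence)
}

#' Write a single-record FASTA file (60-column wrap)
#'
#' @param genome_id Header id.
#' @param sequence DNA string.
#' @param path Output path.
#' @export
write_fasta <- function(genome_id, sequence, path) {
  set <- Biostrings::BStringSet(stats::setNames(sequence, genome_id))
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Read gene annotations from a GFF3 file
#'
#' Keeps `gene` and `CDS` features, requires an `ID` attribute, and
#' converts the 1-based inclusive GFF coordinates to the package's 0-based
#' half-open convention.
#'
#' @param path Path to a GFF3 file.
#' @return Tibble: `gene_id`, `start`, `end`, `strand`.
#' @export
read_gff <- function(path) {
  if (!file.exists(path)) {
    abort_bias(paste0("file not found: ", path), "strandbias_error_io")
  }
  tbl <- readr::read_tsv(
    path, comment = "#",
    col_names = c("seqid", "source", "type", "start", "end",
                  "score", "strand", "phase", "attributes"),
    col_types = readr::cols(
      seqid = "c", source = "c", type = "c", start = "i", end = "i",
      score = "c", strand = "c", phase = "c", attributes = "c"),
    progress = FALSE)
  tbl <- dplyr::filter(tbl, .data$type %in% c("gene", "CDS"))
  if (nrow(tbl) == 0L) return(empty_gene_table())
  ids <- stringr::str_match(tbl$attributes, "(?:^|;)ID=([^;]+)")[, 2L]
  if (anyNA(ids)) {
    abort_bias(sprintf("%s: %d feature(s) lack an ID attribute",
                       path, sum(is.na(ids))), "strandbias_error_parse")
  }
  if (any(tbl$end < tbl$start)) {
    abort_bias(sprintf("%s: feature end < start (origin-wrapping features are not representable in GFF3 here)",
                       path), "strandbias_error_parse")
  }
  if (!all(tbl$strand %in% c("+", "-"))) {
    abort_bias(sprintf("%s: strand must be '+' or '-'", path),
               "strandbias_error_parse")
  }
  tibble::tibble(gene_id = ids, start = tbl$start - 1L, end = tbl$end,
                 strand = tbl$strand)
}

#' Write gene annotations as GFF3
#'
#' @param record A [genome_record()].
#' @param path Output path.
#' @export
write_gff <- function(record, path) {
  genes <- dplyr::arrange(record$genes, .data$start, .data$gene_id)
  lines <- c("##gff-version 3",
             sprintf("##sequence-region %s 1 %d", record$genome_id,
                     record$length),
             sprintf("%s\tstrandbias\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                     record$genome_id, genes$start + 1L, genes$end,
                     genes$strand, genes$gene_id))
  writeLines(lines, path)
  invisible(path)
}

#' Read replication origin/terminus coordinates
#'
#' Accepts either point form (`genome_id`, `ori`, `ter`) or interval form
#' (`genome_id`, `ori_start`, `ori_end`, `ter_start`, `ter_end`), both
#' 0-based. Intervals are collapsed to their midpoints; an interval whose
#' end precedes its start wraps the coordinate origin, and its midpoint is
#' taken modulo the chromosome length (which must then be supplied via
#' `lengths`).
#'
#' @param path Path to the TSV.
#' @param lengths Optional named integer vector of chromosome lengths,
#'   required only when wrapping intervals occur.
#' @return Tibble: `genome_id`, `ori`, `ter`.
#' @export
read_oriter <- function(path, lengths = NULL) {
  tbl <- read_tsv_strict(path, readr::cols(genome_id = "c",
                                           .default = "d"))
  require_columns(tbl, "genome_id", path)
  if (anyDuplicated(tbl$genome_id)) {
    dup <- unique(tbl$genome_id[duplicated(tbl$genome_id)])
    abort_bias(sprintf("%s: duplicate genome_id(s): %s", path,
                       paste(dup, collapse = ", ")),
               "strandbias_error_parse")
  }
  if (all(c("ori", "ter") %in% names(tbl))) {
    out <- dplyr::select(tbl, "genome_id", "ori", "ter")
  } else {
    require_columns(tbl, c("ori_start", "ori_end", "ter_start", "ter_end"),
                    path)
    out <- tibble::tibble(
      genome_id = tbl$genome_id,
      ori = interval_midpoint(tbl$ori_start, tbl$ori_end, tbl$genome_id,
                              lengths, path),
      ter = interval_midpoint(tbl$ter_start, tbl$ter_end, tbl$genome_id,
                              lengths, path))
  }
  dplyr::mutate(out, ori = as.integer(.data$ori), ter = as.integer(.data$ter))
}

interval_midpoint <- function(start, end, ids, lengths, path) {
  wrap <- end < start
  mid <- floor((start + end) / 2)
  if (any(wrap)) {
    if (is.null(lengths)) {
      abort_bias(sprintf("%s: wrapping interval(s) for %s need chromosome lengths",
                         path, paste(ids[wrap], collapse = ", ")),
                 "strandbias_error_parse")
    }
    L <- lengths[ids[wrap]]
    if (anyNA(L)) {
      abort_bias(sprintf("%s: no length supplied for %s", path,
                         paste(ids[wrap][is.na(L)], collapse = ", ")),
                 "strandbias_error_parse")
    }
    span <- (end[wrap] - start[wrap]) %% L
    mid[wrap] <- floor(start[wrap] + span / 2) %% L
  }
  mid
}

#' Read a cohort COG annotation table
#'
#' @param path TSV with columns `genome_id`, `gene_id`, `cog_group_id`,
#'   `subcategories`.
#' @return Tibble with those columns.
#' @export
read_cog <- function(path) {
  tbl <- read_tsv_strict(path, readr::cols(.default = "c"))
  require_columns(tbl, c("genome_id", "gene_id", "cog_group_id",
                         "subcategories"), path)
  bad <- !stringr::str_detect(tbl$subcategories, "^[A-Z]+$")
  if (any(bad)) {
    abort_bias(sprintf("%s: malformed subcategory string(s): %s", path,
                       paste(utils::head(unique(tbl$subcategories[bad]), 5),
                             collapse = ", ")),
               "strandbias_error_parse")
  }
  tbl
}

#' Read a cohort KEGG pathway table
#'
#' @param path TSV with columns `genome_id`, `gene_id`, `pathway_id`.
#' @return Tibble with those columns. Unknown pathway ids raise an error
#'   naming the id.
#' @export
read_kegg <- function(path) {
  tbl <- read_tsv_strict(path, readr::cols(.default = "c"))
  require_columns(tbl, c("genome_id", "gene_id", "pathway_id"), path)
  unknown <- setdiff(unique(tbl$pathway_id), KEGG_RR_PATHWAYS)
  if (length(unknown) > 0L) {
    abort_bias(sprintf("%s: unknown KEGG pathway id(s): %s", path,
                       paste(unknown, collapse = ", ")),
               "strandbias_error_parse")
  }
  tbl
}

#' Read cohort metadata
#'
#' @param path TSV with columns `genome_id`, `phylum`,
#'   `obligate_intracellular` (one of 0/1/true/false), and optional
#'   `s_value`, `generation_time`.
#' @return Tibble with parsed columns.
#' @export
read_metadata <- function(path) {
  tbl <- read_tsv_strict(path, readr::cols(genome_id = "c", phylum = "c",
                                           obligate_intracellular = "c",
                                           .default = "d"))
  require_columns(tbl, c("genome_id", "phylum", "obligate_intracellular"),
                  path)
  if (any(is.na(tbl$phylum) | tbl$phylum == "")) {
    abort_bias(sprintf("%s: empty phylum label(s)", path),
               "strandbias_error_parse")
  }
  flag <- tolower(tbl$obligate_intracellular)
  if (!all(flag %in% c("0", "1", "true", "false"))) {
    abort_bias(sprintf("%s: obligate_intracellular must be 0/1/true/false",
                       path), "strandbias_error_parse")
  }
  tbl$obligate_intracellular <- flag %in% c("1", "true")
  if (!"s_value" %in% names(tbl)) tbl$s_value <- NA_real_
  if (!"generation_time" %in% names(tbl)) tbl$generation_time <- NA_real_
  tbl
}

#' Write a simulated cohort to disk
#'
#' Layout: `genomes/<id>.fasta`, `genomes/<id>.gff`, `oriter.tsv`,
#' `cog.tsv`, `kegg.tsv`, `metadata.tsv`, `truth.tsv`. All writers emit
#' deterministic ordering (genome_id, then coordinate).
#'
#' @param cohort A `bias_cohort` (see [simulate_cohort()]).
#' @param dir Output directory (created if needed).
#' @export
write_cohort <- function(cohort, dir) {
  gdir <- file.path(dir, "genomes")
  dir.create(gdir, recursive = TRUE, showWarnings = FALSE)
  ids <- sort(names(cohort$genomes))
  for (id in ids) {
    rec <- cohort$genomes[[id]]
    write_fasta(rec$genome_id, rec$sequence,
                file.path(gdir, paste0(id, ".fasta")))
    write_gff(rec, file.path(gdir, paste0(id, ".gff")))
  }
  oriter <- tibble::tibble(
    genome_id = ids,
    ori = vapply(cohort$genomes[ids], function(r) r$ori, integer(1)),
    ter = vapply(cohort$genomes[ids], function(r) r$ter, integer(1)))
  readr::write_tsv(oriter, file.path(dir, "oriter.tsv"))
  readr::write_tsv(dplyr::arrange(cohort$cog, .data$genome_id, .data$gene_id),
                   file.path(dir, "cog.tsv"))
  readr::write_tsv(dplyr::arrange(cohort$kegg, .data$genome_id, .data$gene_id),
                   file.path(dir, "kegg.tsv"))
  readr::write_tsv(dplyr::arrange(cohort$metadata, .data$genome_id),
                   file.path(dir, "metadata.tsv"), na = ".")
  if (!is.null(cohort$truth)) {
    readr::write_tsv(dplyr::arrange(cohort$truth, .data$genome_id),
                     file.path(dir, "truth.tsv"), na = ".")
  }
  invisible(dir)
}

#' Load a cohort directory
#'
#' Reads the layout written by [write_cohort()], enforcing cross-file
#' genome_id consistency. Genomes without an origin/terminus entry are
#' skipped with a warning (only genomes with known replication coordinates
#' are analysable); annotation rows naming unknown genomes raise an error
#' listing the offenders.
#'
#' @param dir Cohort directory.
#' @return A `bias_cohort` list (without a ground-truth table unless
#'   `truth.tsv` is present).
#' @export
load_cohort <- function(dir) {
  gdir <- file.path(dir, "genomes")
  fastas <- sort(list.files(gdir, pattern = "\\.fasta$", full.names = TRUE))
  if (length(fastas) == 0L) {
    abort_bias(paste0("no FASTA files under ", gdir), "strandbias_error_io")
  }
  oriter <- read_oriter(file.path(dir, "oriter.tsv"))
  cog <- read_cog(file.path(dir, "cog.tsv"))
  kegg <- read_kegg(file.path(dir, "kegg.tsv"))
  metadata <- read_metadata(file.path(dir, "metadata.tsv"))

  genomes <- list()
  fasta_ids <- character()
  for (fa in fastas) {
    rec_raw <- read_fasta(fa)
    id <- rec_raw$genome_id
    fasta_ids <- c(fasta_ids, id)
    row <- which(oriter$genome_id == id)
    if (length(row) == 0L) {
      warning(sprintf("skipping genome %s: no ori/ter entry", id))
      next
    }
    genes <- read_gff(sub("\\.fasta$", ".gff", fa))
    genomes[[id]] <- genome_record(id, rec_raw$sequence,
                                   oriter$ori[row], oriter$ter[row], genes)
  }
  known <- names(genomes)
  for (nm in c("cog", "kegg", "metadata")) {
    tbl <- get(nm)
    stray <- setdiff(unique(tbl$genome_id), fasta_ids)
    if (length(stray) > 0L) {
      abort_bias(sprintf("%s.tsv references unknown genome_id(s): %s",
                         nm, paste(stray, collapse = ", ")),
                 "strandbias_error_parse")
    }
  }
  truth_path <- file.path(dir, "truth.tsv")
  truth <- if (file.exists(truth_path)) {
    read_tsv_strict(truth_path, readr::cols(genome_id = "c",
                                            obligate = "l",
                                            .default = "d"))
  } else NULL
  structure(
    list(genomes = genomes,
         cog = dplyr::filter(cog, .data$genome_id %in% known),
         kegg = dplyr::filter(kegg, .data$genome_id %in% known),
         metadata = dplyr::filter(metadata, .data$genome_id %in% known),
         truth = truth),
    class = "bias_cohort"
  )
}
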