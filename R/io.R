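#' Read and write the package's tabular formats
#'
#' Thin TSV wrappers so pipeline inputs and outputs round-trip with header
#' rows: indicator tables (cultivar, variable, timepoint, replicate,
#' value), Ct tables, gene maps (gene_id, chromosome, order_index, start,
#' end, strand) and homolog pair lists (pair_id, gene_a, gene_b).
#'
#' @param path file path.
#' @return a tibble.
#' @name coldtol_io
NULL

#' @rdname coldtol_io
#' @export
read_table_tsv <- function(path) readr::read_tsv(path, show_col_types = FALSE)

#' @rdname coldtol_io
#' @param x tibble to write.
#' @export
write_table_tsv <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}

#' Read promoters (or any sequences) from FASTA
#'
#' @param path FASTA file.
#' @return tibble: promoter_id, sequence.
#' @export
read_promoters_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  tibble(promoter_id = names(x), sequence = unname(as.character(x)))
}

#' Write promoters to FASTA
#'
#' @param promoters tibble (promoter_id, sequence) or named character.
#' @param path output file.
#' @export
write_promoters_fasta <- function(promoters, path) {
  if (is.character(promoters)) {
    promoters <- tibble(promoter_id = names(promoters), sequence = unname(promoters))
  }
  x <- Biostrings::DNAStringSet(promoters$sequence)
  names(x) <- promoters$promoter_id
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read codon-aligned sequence pairs from FASTA (two records per pair)
#'
#' Records are taken in order as (ancestor/first, descendant/second) per
#' pair; the pair id is the first record's name stripped of any trailing
#' "_a"/"_1" suffix.
#'
#' @param path FASTA file with an even number of records.
#' @return tibble: pair_id, seq_a, seq_b.
#' @export
read_cds_pairs_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  if (base::length(x) %% 2 != 0) abort("pair FASTA must hold an even number of records")
  odd <- seq(1, base::length(x), by = 2)
  tibble(
    pair_id = sub("_(a|1)$", "", names(x)[odd]),
    seq_a = unname(as.character(x)[odd]),
    seq_b = unname(as.character(x)[odd + 1])
  )
}

#' Write codon-aligned pairs to FASTA (two records per pair)
#'
#' @param pairs tibble: pair_id, seq_a, seq_b.
#' @param path output file.
#' @export
write_cds_pairs_fasta <- function(pairs, path) {
  seqs <- as.vector(rbind(pairs$seq_a, pairs$seq_b))
  nm <- as.vector(rbind(paste0(pairs$pair_id, "_a"), paste0(pairs$pair_id, "_b")))
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- nm
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Write a gene map as GFF3
#'
#' @param gene_map tibble: gene_id, chromosome, order_index, start, end,
#'   strand.
#' @param path output file.
#' @export
write_gene_map_gff3 <- function(gene_map, path) {
  lines <- c("##gff-version 3",
             sprintf("%s\tcoldtol\tgene\t%d\t%d\t.\t%s\t.\tID=%s;order_index=%d",
                     gene_map$chromosome, gene_map$start, gene_map$end,
                     gene_map$strand, gene_map$gene_id, gene_map$order_index))
  writeLines(lines, path)
  invisible(path)
}

#' Write a simulation truth bundle as JSON
#'
#' @param truth a truth object from any `sim_*()` generator.
#' @param path output file.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
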