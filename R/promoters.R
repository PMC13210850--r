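#' Starter cis-element dictionary
#'
#' Thirty canonical plant promoter cis-elements with consensus IUPAC
#' patterns, each assigned to one of five functional classes: hormone
#' responsive, stress responsive, light responsive, development related, or
#' other. Motif definitions in public databases are versioned and vary;
#' this starter set uses widely cited consensus strings and is meant to be
#' replaced or extended via [read_motif_dictionary()] when exact database
#' fidelity matters.
#'
#' @return tibble: element, pattern (IUPAC), class.
#' @export
default_motif_dictionary <- function() {
  path <- system.file("extdata", "cis_elements.yaml", package = "coldtol")
  read_motif_dictionary(path)
}

#' Read a motif dictionary from YAML
#'
#' The file maps each element name to `pattern` (IUPAC nucleotide codes)
#' and `class` (one of hormone, stress, light, development, other).
#'
#' @param path YAML file.
#' @return validated dictionary tibble.
#' @export
read_motif_dictionary <- function(path) {
  raw <- yaml::read_yaml(path)
  dict <- list_rbind(imap(raw, function(entry, nm) {
    tibble(element = nm, pattern = toupper(entry$pattern), class = entry$class)
  }))
  validate_dictionary(dict)
}

validate_dictionary <- function(dictionary) {
  dictionary <- as_tibble(dictionary)
  stopifnot(all(c("element", "pattern", "class") %in% names(dictionary)))
  ok_class <- c("hormone", "stress", "light", "development", "other")
  if (!all(dictionary$class %in% ok_class)) {
    abort(sprintf("classes must be one of: %s", paste(ok_class, collapse = ", ")))
  }
  if (any(grepl("[^ACGTRYSWKMBDHVN]", dictionary$pattern))) {
    abort("patterns must use IUPAC nucleotide codes only")
  }
  per_elem <- dictionary |> distinct(.data$element, .data$class) |> count(.data$element)
  if (any(per_elem$n > 1)) abort("each element must map to exactly one class")
  dictionary
}

#' Scan promoters for cis-element occurrences on both strands
#'
#' Counts every occurrence of every IUPAC pattern: plus-strand hits are
#' forward matches, minus-strand hits are matches of the reverse-complement
#' pattern on the forward sequence. Overlapping occurrences are all
#' counted, palindromic patterns once per strand, and positions are 0-based
#' on the forward strand. N in the subject never matches.
#'
#' @param promoters tibble (promoter_id, sequence) or a named character
#'   vector; sequences over A/C/G/T/N.
#' @param dictionary motif dictionary tibble (element, pattern, class).
#' @return tibble: promoter_id, element, class, start (0-based), strand.
#' @examples
#' scan_promoters(c(p1 = "AAACGTGAA"), tibble::tibble(
#'   element = "ABRE", pattern = "ACGTG", class = "hormone"))
#' @export
scan_promoters <- function(promoters, dictionary) {
  if (is.character(promoters)) {
    promoters <- tibble(promoter_id = names(promoters) %||%
                          as.character(seq_along(promoters)),
                        sequence = unname(promoters))
  }
  dictionary <- validate_dictionary(dictionary)
  seqs <- toupper(promoters$sequence)
  if (any(grepl("[^ACGTN]", seqs))) abort("sequences must be over A, C, G, T, N")
  subjects <- Biostrings::DNAStringSet(seqs)
  names(subjects) <- promoters$promoter_id

  hits <- list()
  for (i in seq_len(nrow(dictionary))) {
    pat_fwd <- dictionary$pattern[i]
    pat_rev <- revcomp(pat_fwd)
    for (j in seq_along(subjects)) {
      m <- Biostrings::matchPattern(pat_fwd, subjects[[j]], fixed = "subject")
      if (base::length(m)) {
        hits[[base::length(hits) + 1L]] <- tibble(
          promoter_id = names(subjects)[j], element = dictionary$element[i],
          class = dictionary$class[i],
          start = Biostrings::start(m) - 1L, strand = "+")
      }
      m2 <- Biostrings::matchPattern(pat_rev, subjects[[j]], fixed = "subject")
      if (base::length(m2)) {
        hits[[base::length(hits) + 1L]] <- tibble(
          promoter_id = names(subjects)[j], element = dictionary$element[i],
          class = dictionary$class[i],
          start = Biostrings::start(m2) - 1L, strand = "-")
      }
    }
  }
  if (!base::length(hits)) {
    return(tibble(promoter_id = character(), element = character(),
                  class = character(), start = integer(), strand = character()))
  }
  list_rbind(hits) |> arrange(.data$promoter_id, .data$start, .data$element)
}

#' Per-promoter element and class counts
#'
#' @param hits output of [scan_promoters()].
#' @param promoters the scanned promoter set (so zero-hit promoters are
#'   kept).
#' @return list with `per_element` (promoter_id, element, class, n) and
#'   `per_class` (promoter_id, class, n) tibbles.
#' @export
element_counts <- function(hits, promoters) {
  ids <- if (is.character(promoters)) {
    names(promoters) %||% as.character(seq_along(promoters))
  } else promoters$promoter_id
  per_element <- hits |> count(.data$promoter_id, .data$element, .data$class) |>
    tidyr::complete(promoter_id = ids, fill = list(n = 0L))
  per_class <- hits |> count(.data$promoter_id, .data$class) |>
    tidyr::complete(promoter_id = ids, fill = list(n = 0L))
  list(per_element = per_element, per_class = per_class)
}

#' Summarize a promoter scan: element totals, class totals, joint fraction
#'
#' Reports total occurrences per element across promoters, per-class
#' totals, the most abundant elements excluding class "other", and the
#' fraction of promoters that contain hormone-, stress- and light-
#' responsive elements — by default all three classes jointly
#' (`joint_mode = "all"`); `"any"` counts promoters with at least one
#' element from the union.
#'
#' @param hits output of [scan_promoters()].
#' @param promoters the scanned promoter set.
#' @param joint_classes classes entering the joint statistic.
#' @param joint_mode "all" (default) or "any".
#' @return list: `per_element_total`, `per_class_total`, `top_elements`
#'   (excluding "other"), `joint` (n_promoters, n_with, fraction,
#'   percentage).
#' @export
summarize_elements <- function(hits, promoters,
                               joint_classes = c("hormone", "stress", "light"),
                               joint_mode = c("all", "any")) {
  joint_mode <- match.arg(joint_mode)
  ids <- if (is.character(promoters)) {
    names(promoters) %||% as.character(seq_along(promoters))
  } else promoters$promoter_id
  per_element_total <- hits |> count(.data$element, .data$class, name = "total") |>
    arrange(dplyr::desc(.data$total))
  per_class_total <- hits |> count(.data$class, name = "total") |>
    arrange(dplyr::desc(.data$total))
  top_elements <- per_element_total |> filter(.data$class != "other")

  present <- hits |> distinct(.data$promoter_id, .data$class) |>
    filter(.data$class %in% joint_classes)
  n_with <- if (joint_mode == "all") {
    present |> count(.data$promoter_id) |>
      filter(.data$n == base::length(joint_classes)) |> nrow()
  } else {
    dplyr::n_distinct(present$promoter_id)
  }
  list(
    per_element_total = per_element_total,
    per_class_total = per_class_total,
    top_elements = top_elements,
    joint = tibble(n_promoters = base::length(ids), n_with = n_with,
                   fraction = n_with / base::length(ids),
                   percentage = 100 * n_with / base::length(ids))
  )
}

#' Slice upstream promoter regions from a genome
#'
#' Extracts `upstream` bases immediately 5' of each gene (half-open
#' coordinates, clipped at contig edges); minus-strand genes take the
#' region 3' of `end` on the forward strand, reverse-complemented.
#'
#' @param genome named character vector (or DNAStringSet) of contig
#'   sequences.
#' @param gene_map tibble with gene_id, chromosome, start, end, strand
#'   (1-based inclusive gene coordinates).
#' @param upstream promoter length in bp (default 2000).
#' @return tibble: promoter_id (gene_id), sequence.
#' @export
extract_promoters <- function(genome, gene_map, upstream = 2000) {
  if (inherits(genome, "DNAStringSet")) genome <- as.character(genome)
  out <- map(seq_len(nrow(gene_map)), function(i) {
    g <- gene_map[i, ]
    contig <- genome[[g$chromosome]]
    if (is.null(contig)) abort(sprintf("chromosome '%s' absent from genome", g$chromosome))
    L <- nchar(contig)
    if (g$strand == "+") {
      from <- max(1, g$start - upstream); to <- g$start - 1
      s <- if (to >= from) substr(contig, from, to) else ""
    } else {
      from <- g$end + 1; to <- min(L, g$end + upstream)
      s <- if (to >= from) revcomp(substr(contig, from, to)) else ""
    }
    tibble(promoter_id = g$gene_id, sequence = s)
  })
  list_rbind(out)
}
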