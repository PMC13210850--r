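# attach each pair's chromosomes and order indices from the gene map,
# canonicalized so chr_a <= chr_b (and o1 <= o2 within a chromosome)
pair_coordinates <- function(gene_map, pairs) {
  stopifnot(all(c("gene_a", "gene_b") %in% names(pairs)))
  look <- setNames(seq_len(nrow(gene_map)), gene_map$gene_id)
  ia <- look[pairs$gene_a]
  ib <- look[pairs$gene_b]
  if (anyNA(ia) || anyNA(ib)) {
    missing <- unique(c(pairs$gene_a[is.na(ia)], pairs$gene_b[is.na(ib)]))
    abort(sprintf("gene id(s) absent from map: %s",
                  paste(utils::head(missing, 5), collapse = ", ")))
  }
  out <- pairs
  out$chr_a <- gene_map$chromosome[ia]
  out$chr_b <- gene_map$chromosome[ib]
  out$o_a <- gene_map$order_index[ia]
  out$o_b <- gene_map$order_index[ib]
  flip <- out$chr_a > out$chr_b | (out$chr_a == out$chr_b & out$o_a > out$o_b)
  tmp_g <- out$gene_a[flip]; out$gene_a[flip] <- out$gene_b[flip]; out$gene_b[flip] <- tmp_g
  tmp_c <- out$chr_a[flip]; out$chr_a[flip] <- out$chr_b[flip]; out$chr_b[flip] <- tmp_c
  tmp_o <- out$o_a[flip]; out$o_a[flip] <- out$o_b[flip]; out$o_b[flip] <- tmp_o
  out
}

#' Tandem duplication calls on a gene map
#'
#' A homolog pair is tandem when both genes lie on the same chromosome
#' within `max_gap` order indices of each other and the pair is not an
#' anchor of any collinear block.
#'
#' @param gene_map tibble: gene_id, chromosome, order_index, ...
#' @param pairs homolog pairs tibble (gene_a, gene_b, optional pair_id).
#' @param max_gap maximum intervening order-index distance (default 10).
#' @param blocks optional [chain_collinear()] result whose anchors are
#'   excluded.
#' @return the pairs tibble with logical column `tandem`.
#' @export
detect_tandem <- function(gene_map, pairs, max_gap = 10, blocks = NULL) {
  co <- pair_coordinates(gene_map, pairs)
  tandem <- co$chr_a == co$chr_b & abs(co$o_a - co$o_b) <= max_gap
  if (!is.null(blocks) && nrow(blocks$anchors %||% tibble())) {
    key <- paste(co$gene_a, co$gene_b)
    akey <- c(paste(blocks$anchors$gene_a, blocks$anchors$gene_b),
              paste(blocks$anchors$gene_b, blocks$anchors$gene_a))
    tandem <- tandem & !(key %in% akey)
  }
  co$tandem <- tandem
  co |> select(dplyr::any_of("pair_id"), "gene_a", "gene_b", "tandem")
}

#' Greedy collinear block chaining on homolog anchors
#'
#' For every chromosome pair, anchors are sorted along the first
#' chromosome and the longest strictly monotone chain (rising or falling on
#' the second chromosome) with successive order-index gaps at most
#' `max_anchor_gap` on both chromosomes is extracted; extraction repeats on
#' the remaining anchors until no chain reaches `min_anchors`. This is a
#' deliberately simple, deterministic chainer in the spirit of
#' anchor-chaining synteny tools, not a re-implementation of any of them.
#'
#' @param gene_map gene map tibble.
#' @param pairs homolog pairs tibble.
#' @param min_anchors minimum anchors per emitted block (default 5).
#' @param max_anchor_gap maximum order-index gap between successive anchors
#'   (default 25).
#' @return list with `blocks` (block_id, chr_a, chr_b, n_anchors,
#'   orientation) and `anchors` (block_id, gene_a, gene_b, o_a, o_b).
#' @export
chain_collinear <- function(gene_map, pairs, min_anchors = 5, max_anchor_gap = 25) {
  co <- pair_coordinates(gene_map, pairs)
  blocks <- list(); anchors <- list(); block_id <- 0L
  for (key in unique(paste(co$chr_a, co$chr_b))) {
    sub <- co[paste(co$chr_a, co$chr_b) == key, , drop = FALSE]
    sub <- sub[order(sub$o_a, sub$o_b), , drop = FALSE]
    repeat {
      if (nrow(sub) < min_anchors) break
      chain <- longest_monotone_chain(sub$o_a, sub$o_b, max_anchor_gap)
      if (base::length(chain$idx) < min_anchors) break
      block_id <- block_id + 1L
      picked <- sub[chain$idx, , drop = FALSE]
      blocks[[block_id]] <- tibble(
        block_id = block_id, chr_a = picked$chr_a[1], chr_b = picked$chr_b[1],
        n_anchors = nrow(picked), orientation = chain$orientation
      )
      anchors[[block_id]] <- tibble(
        block_id = block_id, gene_a = picked$gene_a, gene_b = picked$gene_b,
        o_a = picked$o_a, o_b = picked$o_b
      )
      sub <- sub[-chain$idx, , drop = FALSE]
    }
  }
  if (!block_id) {
    return(list(blocks = tibble(block_id = integer(), chr_a = character(),
                                chr_b = character(), n_anchors = integer(),
                                orientation = character()),
                anchors = tibble(block_id = integer(), gene_a = character(),
                                 gene_b = character(), o_a = integer(),
                                 o_b = integer())))
  }
  list(blocks = list_rbind(blocks), anchors = list_rbind(anchors))
}

# O(n^2) DP for the longest chain strictly increasing in `a` and strictly
# monotone in `b`, with successive gaps <= max_gap on both axes; `a` must be
# sorted ascending. Returns the better of the rising and falling orientations
# (rising wins ties).
longest_monotone_chain <- function(a, b, max_gap) {
  best <- list(idx = integer(0), orientation = "rising")
  for (orient in c("rising", "falling")) {
    n <- base::length(a)
    len <- rep(1L, n); prev <- rep(NA_integer_, n)
    for (i in seq_len(n)) {
      for (j in seq_len(i - 1L)) {
        step_ok <- a[i] > a[j] && a[i] - a[j] <= max_gap &&
          (if (orient == "rising") b[i] > b[j] && b[i] - b[j] <= max_gap
           else b[i] < b[j] && b[j] - b[i] <= max_gap)
        if (step_ok && len[j] + 1L > len[i]) {
          len[i] <- len[j] + 1L
          prev[i] <- j
        }
      }
    }
    if (n) {
      end <- which.max(len)
      idx <- integer(0)
      k <- end
      while (!is.na(k)) { idx <- c(k, idx); k <- prev[k] }
      if (base::length(idx) > base::length(best$idx)) {
        best <- list(idx = idx, orientation = orient)
      }
    }
  }
  best
}

#' Classify duplicated gene pairs into WGD/segmental, tandem and dispersed
#'
#' Pairs that anchor a collinear block are WGD/segmental (block precedence);
#' remaining same-chromosome pairs within the tandem gap are tandem; the
#' rest are dispersed.
#'
#' @param gene_map gene map tibble.
#' @param pairs homolog pairs tibble.
#' @param blocks optional precomputed [chain_collinear()] result (computed
#'   here when NULL).
#' @param max_gap tandem order-index gap (default 10).
#' @param min_anchors,max_anchor_gap chaining parameters when blocks are
#'   computed internally.
#' @return tibble: pair_id (constructed when absent), gene_a, gene_b,
#'   class, block_id (NA unless collinear).
#' @export
classify_duplications <- function(gene_map, pairs, blocks = NULL,
                                  max_gap = 10, min_anchors = 5,
                                  max_anchor_gap = 25) {
  if (is.null(blocks)) {
    blocks <- chain_collinear(gene_map, pairs, min_anchors, max_anchor_gap)
  }
  co <- pair_coordinates(gene_map, pairs)
  if (!"pair_id" %in% names(co)) {
    co$pair_id <- paste(co$gene_a, co$gene_b, sep = "|")
  }
  akey <- if (nrow(blocks$anchors)) {
    setNames(rep(blocks$anchors$block_id, 2),
             c(paste(blocks$anchors$gene_a, blocks$anchors$gene_b),
               paste(blocks$anchors$gene_b, blocks$anchors$gene_a)))
  } else setNames(integer(0), character(0))
  key <- paste(co$gene_a, co$gene_b)
  in_block <- key %in% names(akey)
  tandem <- !in_block & co$chr_a == co$chr_b & abs(co$o_a - co$o_b) <= max_gap
  co |>
    mutate(
      class = dplyr::case_when(in_block ~ "wgd_segmental",
                               tandem ~ "tandem",
                               TRUE ~ "dispersed"),
      block_id = ifelse(in_block, unname(akey[key]), NA_integer_)
    ) |>
    select("pair_id", "gene_a", "gene_b", "class", "block_id")
}

#' Selection-pressure summary per duplication class
#'
#' Joins Ka/Ks estimates to duplication calls and tallies, per class and
#' overall: pairs with ratio < 1 (purifying), ratio > 1 (positive),
#' undefined ratios, and the mean ratio over defined values.
#'
#' @param estimates [kaks_estimate()] output (pair_id, ka, ks, ratio, ...).
#' @param calls [classify_duplications()] output (pair_id, class), or any
#'   tibble with those columns.
#' @return tibble: class ("all" row last), n, n_purifying, n_positive,
#'   n_undefined, mean_ratio.
#' @export
selection_summary <- function(estimates, calls) {
  stopifnot("pair_id" %in% names(estimates), "pair_id" %in% names(calls))
  joined <- inner_join(estimates, calls |> select("pair_id", "class"),
                       by = "pair_id")
  summ <- function(df, label) {
    tibble(
      class = label,
      n = nrow(df),
      n_purifying = sum(!is.na(df$ratio) & df$ratio < 1),
      n_positive = sum(!is.na(df$ratio) & df$ratio > 1),
      n_undefined = sum(is.na(df$ratio)),
      mean_ratio = if (any(!is.na(df$ratio))) mean(df$ratio, na.rm = TRUE) else NA_real_
    )
  }
  per_class <- joined |>
    dplyr::group_split(.data$class) |>
    map(function(df) summ(df, df$class[1])) |>
    list_rbind()
  bind_rows(per_class, summ(joined, "all"))
}
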