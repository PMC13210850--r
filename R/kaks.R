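# --- codon machinery (standard genetic code) ------------------------------
# built once per session; shared by the estimator and the codon simulator

.codon_env <- new.env(parent = emptyenv())

codon_tables <- function() {
  if (!is.null(.codon_env$tab)) return(.codon_env$tab)
  gc_tab <- Biostrings::GENETIC_CODE
  codons <- names(gc_tab)
  aa <- unname(gc_tab)
  sense <- codons[aa != "*"]
  aa_sense <- aa[aa != "*"]
  n <- base::length(sense)  # 61
  bases <- c("A", "C", "G", "T")

  idx_of <- setNames(seq_len(n), sense)
  # all single-base mutants of each sense codon
  neighbors <- vector("list", n)
  n_syn_nb <- numeric(n)
  n_nonsyn_nb <- numeric(n)
  sites_syn <- numeric(n)
  syn_lookup <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    cod <- strsplit(sense[i], "")[[1]]
    nb_idx <- integer(0)
    nb_syn <- logical(0)
    s_codon <- 0
    for (pos in 1:3) {
      mut_codons <- vapply(setdiff(bases, cod[pos]), function(b) {
        m <- cod; m[pos] <- b; paste(m, collapse = "")
      }, character(1))
      mut_aa <- gc_tab[mut_codons]
      non_stop <- mut_aa != "*"
      syn <- mut_aa == aa_sense[i] & non_stop
      # NG86 site fraction: synonymous share among non-stop mutations
      if (any(non_stop)) s_codon <- s_codon + sum(syn) / sum(non_stop)
      keep <- mut_codons[non_stop]
      nb_idx <- c(nb_idx, idx_of[keep])
      nb_syn <- c(nb_syn, syn[non_stop])
    }
    neighbors[[i]] <- list(idx = unname(nb_idx), syn = unname(nb_syn))
    n_syn_nb[i] <- sum(nb_syn)
    n_nonsyn_nb[i] <- sum(!nb_syn)
    sites_syn[i] <- s_codon
    syn_lookup[i, nb_idx] <- nb_syn
  }

  .codon_env$tab <- list(
    sense_codons = sense, aa = aa_sense, idx_of = idx_of,
    neighbors = neighbors, n_syn_nb = n_syn_nb, n_nonsyn_nb = n_nonsyn_nb,
    sites_syn = sites_syn, sites_nonsyn = 3 - sites_syn,
    syn_lookup = syn_lookup, gc_tab = gc_tab
  )
  .codon_env$tab
}

# average synonymous/nonsynonymous difference counts between two sense
# codons over all minimal mutational pathways that avoid stop codons
codon_pair_diff <- function(c1, c2, tab = codon_tables()) {
  if (c1 == c2) return(c(sd = 0, nd = 0))
  a1 <- strsplit(c1, "")[[1]]
  a2 <- strsplit(c2, "")[[1]]
  diff_pos <- which(a1 != a2)
  paths <- if (base::length(diff_pos) == 1L) {
    list(diff_pos)
  } else {
    perms <- permutations_of(diff_pos)
    perms
  }
  gc_tab <- tab$gc_tab
  totals <- list()
  for (ord in paths) {
    cur <- a1
    sd <- 0; nd <- 0
    ok <- TRUE
    for (pos in ord) {
      nxt <- cur; nxt[pos] <- a2[pos]
      cod_from <- paste(cur, collapse = "")
      cod_to <- paste(nxt, collapse = "")
      if (gc_tab[cod_to] == "*") { ok <- FALSE; break }
      if (gc_tab[cod_from] == gc_tab[cod_to]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    if (ok) totals[[base::length(totals) + 1L]] <- c(sd = sd, nd = nd)
  }
  if (!base::length(totals)) {
    # no stop-free minimal pathway (rare); fall back to all pathways
    for (ord in paths) {
      cur <- a1
      sd <- 0; nd <- 0
      for (pos in ord) {
        nxt <- cur; nxt[pos] <- a2[pos]
        if (gc_tab[paste(cur, collapse = "")] == gc_tab[paste(nxt, collapse = "")]) {
          sd <- sd + 1
        } else nd <- nd + 1
        cur <- nxt
      }
      totals[[base::length(totals) + 1L]] <- c(sd = sd, nd = nd)
    }
  }
  Reduce(`+`, totals) / base::length(totals)
}

permutations_of <- function(v) {
  if (base::length(v) == 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in permutations_of(v[-i])) out[[base::length(out) + 1L]] <- c(v[i], rest)
  }
  out
}

# memoized 61 x 61 tables of averaged pathway differences
codon_diff_tables <- function() {
  if (!is.null(.codon_env$diff)) return(.codon_env$diff)
  tab <- codon_tables()
  n <- base::length(tab$sense_codons)
  sd_m <- matrix(0, n, n)
  nd_m <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- codon_pair_diff(tab$sense_codons[i], tab$sense_codons[j], tab)
      sd_m[i, j] <- sd_m[j, i] <- d["sd"]
      nd_m[i, j] <- nd_m[j, i] <- d["nd"]
    }
  }
  .codon_env$diff <- list(sd = sd_m, nd = nd_m)
  .codon_env$diff
}

#' Synonymous and nonsynonymous site counts of a codon (NG86)
#'
#' For each of the three positions, the synonymous fraction is the share of
#' the single-base mutations that preserve the amino acid, with mutations
#' into stop codons excluded from the denominator; the three fractions sum
#' with their complements to 3 sites per codon.
#'
#' @param codon a sense codon (3-mer over ACGT).
#' @return named vector: syn, nonsyn (summing to 3).
#' @examples
#' ng86_sites("TTT")  # c(syn = 1/3, nonsyn = 8/3)
#' @export
ng86_sites <- function(codon) {
  codon <- toupper(codon)
  tab <- codon_tables()
  i <- tab$idx_of[codon]
  if (is.na(i)) abort(sprintf("'%s' is not a sense codon", codon))
  c(syn = tab$sites_syn[i], nonsyn = tab$sites_nonsyn[i])
}

#' Nei-Gojobori (1986) Ka/Ks for one codon-aligned pair
#'
#' Sites are counted per codon (averaged over the two sequences); per
#' differing codon, synonymous and nonsynonymous differences are averaged
#' over all minimal mutational pathways that avoid stop codons; the
#' proportions are corrected with the one-parameter (Jukes-Cantor) distance
#' d = -3/4 log(1 - 4p/3). The ratio is undefined when Ks = 0 or when
#' either proportion reaches saturation (p >= 3/4).
#'
#' @param seq_a,seq_b gapless in-frame coding sequences of equal length
#'   (multiple of 3), no internal stop codons.
#' @return tibble: ka, ks, ratio, p_syn, p_nonsyn, s_sites, n_sites,
#'   s_diff, n_diff, undefined_reason (NA when the ratio is defined).
#' @export
ng86_pair <- function(seq_a, seq_b) {
  seq_a <- toupper(seq_a); seq_b <- toupper(seq_b)
  if (nchar(seq_a) != nchar(seq_b)) abort("sequences differ in length")
  if (nchar(seq_a) %% 3 != 0) abort("length not a multiple of 3")
  if (nchar(seq_a) < 3) abort("need at least one codon")
  tab <- codon_tables()
  split_codons <- function(s) substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
  ca <- split_codons(seq_a)
  cb <- split_codons(seq_b)
  ia <- tab$idx_of[ca]
  ib <- tab$idx_of[cb]
  if (anyNA(ia) || anyNA(ib)) abort("sequences contain stop codons or invalid codons")

  S <- (sum(tab$sites_syn[ia]) + sum(tab$sites_syn[ib])) / 2
  N <- (sum(tab$sites_nonsyn[ia]) + sum(tab$sites_nonsyn[ib])) / 2
  diff_tab <- codon_diff_tables()
  idx <- cbind(ia, ib)
  Sd <- sum(diff_tab$sd[idx])
  Nd <- sum(diff_tab$nd[idx])

  p_s <- Sd / S
  p_n <- Nd / N
  jc <- function(p) if (p < 0.75) -0.75 * log(1 - 4 * p / 3) else NA_real_
  ks <- jc(p_s)
  ka <- jc(p_n)
  reason <- NA_character_
  ratio <- NA_real_
  if (is.na(ka) || is.na(ks)) {
    reason <- "saturated (p >= 3/4)"
  } else if (ks == 0) {
    reason <- "Ks=0"
  } else {
    ratio <- ka / ks
  }
  tibble(ka = ka, ks = ks, ratio = ratio, p_syn = p_s, p_nonsyn = p_n,
         s_sites = S, n_sites = N, s_diff = Sd, n_diff = Nd,
         undefined_reason = reason)
}

#' Ka/Ks estimates for a table of codon-aligned pairs
#'
#' @param pairs tibble with pair_id, seq_a, seq_b (as from
#'   [sim_cds_pairs()] or [read_cds_pairs_fasta()]).
#' @return tibble: pair_id plus the [ng86_pair()] columns.
#' @export
kaks_estimate <- function(pairs) {
  stopifnot(all(c("pair_id", "seq_a", "seq_b") %in% names(pairs)))
  out <- map(seq_len(nrow(pairs)), function(i) {
    ng86_pair(pairs$seq_a[i], pairs$seq_b[i]) |>
      mutate(pair_id = pairs$pair_id[i], .before = 1)
  })
  list_rbind(out)
}
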