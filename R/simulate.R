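#' Simulate a physiological indicator panel driven by latent cold tolerance
#'
#' Generates the five-indicator panel (SOD, POD, soluble sugar, soluble
#' protein, MDA) for a set of cultivars sampled over a cold time course.
#' Each cultivar carries a latent tolerance `theta` in \[0, 1\]; indicator
#' means at stress timepoints follow a logistic curve in `theta`, rising for
#' the four benefit indicators and falling for MDA (a lipid-peroxidation
#' marker). Replicate noise is multiplicative log-normal with the requested
#' coefficient of variation, so `noise_cv = 0` returns the exact means.
#'
#' @param n_cultivars number of cultivars (>= 3 unless `theta` is supplied).
#' @param timepoints sampling days; day 0 is the unstressed baseline.
#' @param n_replicates biological replicates per cultivar x timepoint.
#' @param noise_cv replicate coefficient of variation (0 = noiseless).
#' @param seed integer seed; identical seeds give identical tables.
#' @param theta optional vector of latent tolerances in \[0, 1\] (one per
#'   cultivar); drawn uniformly when `NULL`.
#' @return list with `indicators` (tibble: cultivar, variable, timepoint,
#'   replicate, value) and `truth` (tibble: cultivar, theta).
#' @examples
#' sim <- sim_physiology(n_cultivars = 4, n_replicates = 2, seed = 1)
#' head(sim$indicators)
#' @export
sim_physiology <- function(n_cultivars,
                           timepoints = c(0, 1, 3, 5, 7),
                           n_replicates = 5,
                           noise_cv = 0.1,
                           seed,
                           theta = NULL) {
  n_cultivars <- check_count(n_cultivars, "n_cultivars", min = if (is.null(theta)) 3L else 2L)
  n_replicates <- check_count(n_replicates, "n_replicates")
  noise_cv <- check_fraction(noise_cv, "noise_cv")
  if (!is.null(theta)) {
    stopifnot(length(theta) == n_cultivars, all(theta >= 0 & theta <= 1))
  }

  specs <- indicator_specs()
  with_seed(seed, {
    if (is.null(theta)) theta <- runif(n_cultivars)
    cultivars <- sprintf("cv%02d", seq_len(n_cultivars))
    ramp <- timepoints / max(timepoints)          # 0 at baseline, 1 at last day
    g <- stats::plogis(4 * (theta - 0.5))         # logistic tolerance response

    grid <- tidyr::expand_grid(
      cultivar = cultivars,
      variable = specs$variable,
      timepoint = timepoints,
      replicate = seq_len(n_replicates)
    )
    grid <- grid |>
      left_join(specs, by = "variable") |>
      left_join(tibble(cultivar = cultivars, g = g), by = "cultivar") |>
      mutate(
        ramp = .data$timepoint / max(timepoints),
        resp = ifelse(.data$direction > 0, .data$g, 1 - .data$g),
        mu = .data$baseline * (1 + .data$ramp * (0.2 + 1.5 * .data$resp))
      )
    sdlog <- sqrt(log(1 + noise_cv^2))
    grid$value <- if (noise_cv > 0) {
      grid$mu * rlnorm(nrow(grid), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    } else {
      grid$mu
    }
    list(
      indicators = grid |> select("cultivar", "variable", "timepoint", "replicate", "value"),
      truth = tibble(cultivar = cultivars, theta = theta)
    )
  })
}

#' Directions and units of the five physiological indicators
#'
#' SOD and POD are antioxidant enzyme activities, soluble sugar and soluble
#' protein are osmolyte contents (all rising with cold tolerance); MDA is a
#' membrane-damage marker that falls with tolerance.
#'
#' @return tibble with columns variable, direction (+1 benefit / -1 cost),
#'   unit and the generator's baseline level.
#' @export
indicator_specs <- function() {
  tibble(
    variable = c("SOD", "POD", "soluble_sugar", "soluble_protein", "MDA"),
    direction = c(1, 1, 1, 1, -1),
    unit = c("U/g", "U/g", "mg/g", "mg/g", "nmol/g"),
    baseline = c(250, 300, 12, 8, 6)
  )
}

#' Simulate a tissue expression atlas with planted specific and silent genes
#'
#' Produces a genes x tissues abundance matrix (TPM-like) in which a chosen
#' number of genes per tissue are tissue-specific by construction (true tau
#' above 0.8), a chosen number are completely silent, and the remainder are
#' broadly expressed background.
#'
#' @param n_genes total genes.
#' @param tissues tissue labels.
#' @param n_specific_per_tissue planted specific genes per tissue.
#' @param n_silent planted all-zero genes.
#' @param leakage relative expression of a specific gene outside its home
#'   tissue (0 gives tau exactly 1).
#' @param seed integer seed.
#' @return list with `expression` (tibble: gene_id + one column per tissue)
#'   and `truth` (list: specific_genes tibble, silent_genes character).
#' @export
sim_expression_atlas <- function(n_genes,
                                 tissues = c("root", "stem", "leaf", "flower",
                                             "stolon", "flower_pedicel"),
                                 n_specific_per_tissue = 5,
                                 n_silent = 4,
                                 leakage = 0.05,
                                 seed) {
  n_genes <- check_count(n_genes, "n_genes")
  n_specific_per_tissue <- check_count(n_specific_per_tissue, "n_specific_per_tissue", min = 0L)
  n_silent <- check_count(n_silent, "n_silent", min = 0L)
  leakage <- check_fraction(leakage, "leakage", max = 0.15)
  n_planted <- n_specific_per_tissue * length(tissues) + n_silent
  if (n_planted > n_genes) {
    abort("planted specific + silent genes exceed n_genes")
  }

  with_seed(seed, {
    gene_ids <- sprintf("gene%04d", seq_len(n_genes))
    ids <- sample(gene_ids)  # assign planted roles at random positions
    specific <- tibble(
      gene_id = ids[seq_len(n_specific_per_tissue * length(tissues))],
      tissue = rep(tissues, each = n_specific_per_tissue)
    )
    silent <- ids[n_specific_per_tissue * length(tissues) + seq_len(n_silent)]

    expr <- matrix(
      rlnorm(n_genes * length(tissues), meanlog = log(20), sdlog = 0.3),
      nrow = n_genes, dimnames = list(gene_ids, tissues)
    )
    for (i in seq_len(nrow(specific))) {
      dominant <- rlnorm(1, meanlog = log(150), sdlog = 0.3)
      row <- dominant * leakage * runif(length(tissues), 0.2, 1)
      row[tissues == specific$tissue[i]] <- dominant
      expr[specific$gene_id[i], ] <- row
    }
    expr[silent, ] <- 0

    list(
      expression = tibble(gene_id = gene_ids) |> dplyr::bind_cols(as_tibble(expr)),
      truth = list(specific_genes = specific, silent_genes = silent)
    )
  })
}

#' Simulate a cold-stress expression time course with transient induction
#'
#' Generates replicate abundances at 0, 12 and 24 h in which a planted set of
#' genes shows the transient increase-then-decrease trajectory typical of
#' early cold-responsive transcription factors: the 12 h mean sits exactly
#' `induction_log2fc` doublings above baseline on the pseudocounted scale
#' used by the downstream screen, and the 24 h mean lies between baseline and
#' peak. Non-induced genes have constant means.
#'
#' @param n_genes total genes.
#' @param n_induced planted induced genes.
#' @param induction_log2fc planted log2 fold change at the 12 h peak.
#' @param timepoints hours; first element is the baseline.
#' @param n_replicates replicates per timepoint.
#' @param noise_cv replicate coefficient of variation.
#' @param pseudocount pseudocount convention shared with [cold_screen()].
#' @param seed integer seed.
#' @return list with `expression` (long tibble: gene_id, timepoint,
#'   replicate, value) and `truth` (character vector of induced gene ids).
#' @export
sim_cold_timecourse <- function(n_genes,
                                n_induced,
                                induction_log2fc = 2,
                                timepoints = c(0, 12, 24),
                                n_replicates = 3,
                                noise_cv = 0.1,
                                pseudocount = 1,
                                seed) {
  n_genes <- check_count(n_genes, "n_genes")
  n_induced <- check_count(n_induced, "n_induced", min = 0L)
  if (n_induced > n_genes) abort("n_induced exceeds n_genes")
  check_fraction(induction_log2fc, "induction_log2fc")
  noise_cv <- check_fraction(noise_cv, "noise_cv")

  with_seed(seed, {
    gene_ids <- sprintf("gene%04d", seq_len(n_genes))
    induced <- sample(gene_ids, n_induced)
    baseline <- setNames(rlnorm(n_genes, meanlog = log(50), sdlog = 0.5), gene_ids)

    grid <- tidyr::expand_grid(
      gene_id = gene_ids,
      timepoint = timepoints,
      replicate = seq_len(n_replicates)
    )
    b <- baseline[grid$gene_id]
    mu <- b
    peak_t <- timepoints[2]
    last_t <- timepoints[3]
    is_ind <- grid$gene_id %in% induced
    # plant effects on the pseudocounted scale so the screen's log2FC is exact
    mu[is_ind & grid$timepoint == peak_t] <-
      (b[is_ind & grid$timepoint == peak_t] + pseudocount) * 2^induction_log2fc - pseudocount
    mu[is_ind & grid$timepoint == last_t] <-
      (b[is_ind & grid$timepoint == last_t] + pseudocount) * 2^(induction_log2fc / 2) - pseudocount
    sdlog <- sqrt(log(1 + noise_cv^2))
    grid$value <- if (noise_cv > 0) {
      mu * rlnorm(nrow(grid), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    } else {
      as.numeric(mu)
    }
    list(expression = grid, truth = sort(induced))
  })
}

#' Simulate a qPCR Ct table with known fold changes
#'
#' Builds a cycle-threshold table for a target gene and a stable reference
#' gene over cultivars and timepoints, with a planted true fold change per
#' condition relative to the 0 h calibrator. Target Ct is the calibrator Ct
#' minus log2(fold) plus Gaussian noise; the reference Ct is constant in
#' expectation, so the downstream 2^-ddCt round-trips the planted folds
#' exactly when `ct_sd = 0`.
#'
#' @param cultivars cultivar labels.
#' @param timepoints hours, first is the calibrator.
#' @param true_fold tibble (cultivar, timepoint, fold) of planted fold
#'   changes; missing combinations default to 1.
#' @param n_bio,n_tech biological and technical replicates.
#' @param ct_sd Gaussian Ct noise (cycles) applied per technical measurement.
#' @param gene,reference_gene labels for the target and reference rows.
#' @param seed integer seed.
#' @return tibble with columns sample_id, cultivar, timepoint, gene, role,
#'   bio_rep, tech_rep, ct.
#' @export
sim_qpcr <- function(cultivars = c("DR-2", "Qingshu9", "Favorita"),
                     timepoints = c(0, 12, 24),
                     true_fold = NULL,
                     n_bio = 3,
                     n_tech = 3,
                     ct_sd = 0.2,
                     gene = "target",
                     reference_gene = "StActin",
                     seed) {
  n_bio <- check_count(n_bio, "n_bio")
  n_tech <- check_count(n_tech, "n_tech")
  ct_sd <- check_fraction(ct_sd, "ct_sd")
  folds <- tidyr::expand_grid(cultivar = cultivars, timepoint = timepoints)
  folds$fold <- 1
  if (!is.null(true_fold)) {
    stopifnot(all(c("cultivar", "timepoint", "fold") %in% names(true_fold)))
    if (any(true_fold$fold <= 0)) abort("planted folds must be positive")
    folds <- folds |>
      dplyr::rows_update(as_tibble(true_fold), by = c("cultivar", "timepoint"))
  }

  with_seed(seed, {
    cal_ct <- 24  # calibrator-condition target Ct
    ref_ct <- 18
    grid <- tidyr::expand_grid(
      cultivar = cultivars, timepoint = timepoints,
      bio_rep = seq_len(n_bio), tech_rep = seq_len(n_tech)
    ) |>
      left_join(folds, by = c("cultivar", "timepoint"))
    target <- grid |>
      mutate(gene = gene, role = "target",
             ct = cal_ct - log2(.data$fold) + rnorm(dplyr::n(), sd = ct_sd))
    reference <- grid |>
      mutate(gene = reference_gene, role = "reference",
             ct = ref_ct + rnorm(dplyr::n(), sd = ct_sd))
    bind_rows(target, reference) |>
      mutate(sample_id = sprintf("%s_t%g_b%d", .data$cultivar, .data$timepoint, .data$bio_rep)) |>
      select("sample_id", "cultivar", "timepoint", "gene", "role",
             "bio_rep", "tech_rep", "ct") |>
      arrange(.data$cultivar, .data$timepoint, .data$gene, .data$bio_rep, .data$tech_rep)
  })
}

#' Simulate promoter sequences with planted cis-elements
#'
#' Generates i.i.d. background sequence at a target GC content and inserts
#' concrete instances of IUPAC cis-element patterns at recorded,
#' non-overlapping positions; minus-strand plants are reverse-complemented
#' before insertion. Optionally rejection-samples the background so that no
#' dictionary pattern occurs outside the planted positions.
#'
#' @param n_promoters number of promoters.
#' @param length promoter length in bp (2000 by default, the conventional
#'   upstream window).
#' @param dictionary motif dictionary tibble (element, pattern, class).
#' @param plants tibble (promoter_id, element, strand) of requested
#'   insertions; positions are chosen at random without overlap.
#' @param gc background GC fraction.
#' @param scrub_background if TRUE, re-randomize any background window that
#'   matches a dictionary pattern so downstream scans report exactly the
#'   planted hits.
#' @param seed integer seed.
#' @return list with `promoters` (tibble: promoter_id, sequence) and `truth`
#'   (tibble: promoter_id, element, start (0-based), strand, instance).
#' @export
sim_promoters <- function(n_promoters,
                          length = 2000,
                          dictionary = default_motif_dictionary(),
                          plants = NULL,
                          gc = 0.4,
                          scrub_background = FALSE,
                          seed) {
  n_promoters <- check_count(n_promoters, "n_promoters")
  length <- check_count(length, "length")
  gc <- check_fraction(gc, "gc", max = 1)
  dictionary <- validate_dictionary(dictionary)
  if (any(nchar(dictionary$pattern) > length)) {
    abort("a dictionary motif is longer than the promoter length")
  }
  ids <- sprintf("prom%03d", seq_len(n_promoters))
  if (!is.null(plants)) {
    stopifnot(all(c("promoter_id", "element", "strand") %in% names(plants)))
    if (!all(plants$promoter_id %in% ids)) abort("plant refers to unknown promoter id")
    if (!all(plants$element %in% dictionary$element)) abort("plant refers to unknown element")
    if (!all(plants$strand %in% c("+", "-"))) abort("strand must be '+' or '-'")
  }

  base_prob <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  with_seed(seed, {
    seqs <- vapply(seq_len(n_promoters), function(i) {
      paste(sample(names(base_prob), length, replace = TRUE, prob = base_prob),
            collapse = "")
    }, character(1))
    names(seqs) <- ids

    truth <- tibble(promoter_id = character(), element = character(),
                    start = integer(), strand = character(), instance = character())
    if (!is.null(plants) && nrow(plants)) {
      for (pid in unique(plants$promoter_id)) {
        want <- plants[plants$promoter_id == pid, ]
        occupied <- integer(0)
        for (k in seq_len(nrow(want))) {
          pat <- dictionary$pattern[dictionary$element == want$element[k]][1]
          inst <- instantiate_iupac(pat)
          if (want$strand[k] == "-") inst <- revcomp(inst)
          w <- nchar(inst)
          free <- setdiff(seq_len(length - w + 1),
                          unlist(lapply(occupied, function(s) (s - w + 1):(s + w - 1))))
          free <- free[free >= 1]
          if (!base::length(free)) abort("planted motifs do not fit without overlap")
          pos <- if (base::length(free) == 1L) free else sample(free, 1)
          substr(seqs[pid], pos, pos + w - 1) <- inst
          occupied <- c(occupied, pos:(pos + w - 1))
          truth <- bind_rows(truth, tibble(
            promoter_id = pid, element = want$element[k],
            start = pos - 1L, strand = want$strand[k], instance = inst
          ))
        }
      }
    }

    if (scrub_background) {
      seqs <- scrub_motifs(seqs, dictionary, truth, base_prob)
    }
    list(promoters = tibble(promoter_id = ids, sequence = unname(seqs)),
         truth = truth)
  })
}

# replace any off-plant dictionary match with fresh random bases until clean
scrub_motifs <- function(seqs, dictionary, truth, base_prob, max_iter = 100) {
  for (iter in seq_len(max_iter)) {
    hits <- scan_promoters(tibble(promoter_id = names(seqs), sequence = unname(seqs)),
                           dictionary)
    if (nrow(truth)) {
      hits <- dplyr::anti_join(hits, truth,
                               by = c("promoter_id", "element", "start", "strand"))
    }
    if (!nrow(hits)) return(seqs)
    touched <- FALSE
    for (i in seq_len(nrow(hits))) {
      pid <- hits$promoter_id[i]
      w <- nchar(dictionary$pattern[dictionary$element == hits$element[i]][1])
      s <- hits$start[i] + 1L
      tr <- truth[truth$promoter_id == pid, ]
      overlaps_plant <- nrow(tr) && any(s <= tr$start + nchar(tr$instance) &
                                          (s + w - 1) >= tr$start + 1L)
      if (overlaps_plant) next
      repl <- paste(sample(names(base_prob), w, replace = TRUE, prob = base_prob),
                    collapse = "")
      substr(seqs[pid], s, s + w - 1) <- repl
      touched <- TRUE
    }
    if (!touched) return(seqs)  # only plant-overlapping incidental hits remain
  }
  abort("could not scrub background motifs within iteration budget")
}

instantiate_iupac <- function(pattern) {
  sets <- iupac_sets()
  chars <- strsplit(pattern, "")[[1]]
  paste(vapply(chars, function(ch) {
    opts <- sets[[ch]]
    if (base::length(opts) == 1L) opts else sample(opts, 1)
  }, character(1)), collapse = "")
}

iupac_sets <- function() {
  list(A = "A", C = "C", G = "G", T = "T",
       R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
       K = c("G", "T"), M = c("A", "C"),
       B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
       V = c("A", "C", "G"), N = c("A", "C", "G", "T"))
}

revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A",
            R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
            B = "V", V = "B", D = "H", H = "D", N = "N")
  vapply(x, function(s) {
    paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Simulate codon-aligned sequence pairs at a known Ka/Ks
#'
#' Evolves each descendant from a random ancestral sequence under a
#' continuous-time codon substitution process with equal base
#' exchangeabilities in which nonsynonymous changes are scaled by `omega`;
#' mutations into stop codons are disallowed, so the true
#' nonsynonymous/synonymous rate ratio equals `omega` and the realized
#' substitution history is recorded per pair.
#'
#' @param n_pairs number of pairs.
#' @param n_codons codons per sequence.
#' @param omega planted Ka/Ks (>= 0).
#' @param t expected substitutions per codon along the branch.
#' @param seed integer seed.
#' @return list with `pairs` (tibble: pair_id, seq_a (ancestor), seq_b
#'   (descendant)) and `truth` (tibble: pair_id, omega, n_syn, n_nonsyn
#'   realized substitution counts).
#' @export
sim_cds_pairs <- function(n_pairs, n_codons, omega, t, seed) {
  n_pairs <- check_count(n_pairs, "n_pairs")
  n_codons <- check_count(n_codons, "n_codons")
  omega <- check_fraction(omega, "omega")
  t <- check_fraction(t, "t")
  tab <- codon_tables()

  # per-codon leaving rates at unit scale: syn neighbours * 1 + nonsyn * omega
  rate_unit <- tab$n_syn_nb + omega * tab$n_nonsyn_nb
  mu <- if (t > 0) t / mean(rate_unit) else 0

  with_seed(seed, {
    n_total <- n_pairs * n_codons
    anc <- sample.int(61L, n_total, replace = TRUE)
    cur <- anc
    nsyn <- integer(n_total)
    nnon <- integer(n_total)
    if (mu > 0) {
      time_left <- rep(1, n_total)
      active <- seq_len(n_total)
      while (base::length(active)) {
        rates <- mu * rate_unit[cur[active]]
        active <- active[rates > 0]  # absorbing codons (no allowed moves)
        rates <- rates[rates > 0]
        if (!base::length(active)) break
        dt <- stats::rexp(base::length(active), rate = rates)
        ok <- dt < time_left[active]
        time_left[active] <- time_left[active] - dt
        jump <- active[ok]
        if (base::length(jump)) {
          for (j in jump) {
            ci <- cur[j]
            nb <- tab$neighbors[[ci]]
            w <- ifelse(nb$syn, 1, omega)
            pick <- nb$idx[sample.int(base::length(w), 1L, prob = w)]
            if (tab$syn_lookup[ci, pick]) nsyn[j] <- nsyn[j] + 1L else nnon[j] <- nnon[j] + 1L
            cur[j] <- pick
          }
        }
        active <- jump
      }
    }
    codon_str <- tab$sense_codons
    pair_id <- sprintf("pair%04d", seq_len(n_pairs))
    idx <- matrix(seq_len(n_total), nrow = n_codons)
    seq_a <- vapply(seq_len(n_pairs), function(p)
      paste(codon_str[anc[idx[, p]]], collapse = ""), character(1))
    seq_b <- vapply(seq_len(n_pairs), function(p)
      paste(codon_str[cur[idx[, p]]], collapse = ""), character(1))
    grp <- rep(seq_len(n_pairs), each = n_codons)
    list(
      pairs = tibble(pair_id = pair_id, seq_a = seq_a, seq_b = seq_b),
      truth = tibble(
        pair_id = pair_id, omega = omega,
        n_syn = as.integer(tapply(nsyn, grp, sum)),
        n_nonsyn = as.integer(tapply(nnon, grp, sum))
      )
    )
  })
}

#' Simulate a gene map with planted tandem arrays and collinear blocks
#'
#' Lays out genes on chromosomes with consecutive order indices and plants
#' (a) tandem arrays, whose members yield all pairwise same-chromosome
#' homolog pairs at adjacent order indices, (b) collinear blocks, runs of
#' anchor pairs in consistent order across two chromosomes, and (c)
#' dispersed decoy pairs placed off-structure.
#'
#' @param n_chromosomes number of chromosomes.
#' @param genes_per_chr genes per chromosome.
#' @param tandem_arrays tibble (chr, start, size): array of `size` adjacent
#'   genes starting at order index `start` on chromosome `chr`.
#' @param collinear_blocks tibble (chr_a, chr_b, start_a, start_b, length):
#'   anchors pair order `start_a + i` on `chr_a` with `start_b + i` on
#'   `chr_b` for i = 0..length-1.
#' @param n_dispersed decoy homolog pairs on different chromosomes.
#' @param seed integer seed.
#' @return list with `gene_map` (tibble: gene_id, chromosome, order_index,
#'   start, end, strand), `pairs` (tibble: pair_id, gene_a, gene_b) and
#'   `truth` (tibble: pair_id, class in wgd_segmental/tandem/dispersed).
#' @export
sim_gene_map <- function(n_chromosomes,
                         genes_per_chr,
                         tandem_arrays = NULL,
                         collinear_blocks = NULL,
                         n_dispersed = 0,
                         seed) {
  n_chromosomes <- check_count(n_chromosomes, "n_chromosomes")
  genes_per_chr <- check_count(genes_per_chr, "genes_per_chr")
  n_dispersed <- check_count(n_dispersed, "n_dispersed", min = 0L)

  gene_map <- tidyr::expand_grid(chromosome = sprintf("chr%02d", seq_len(n_chromosomes)),
                                 order_index = seq_len(genes_per_chr)) |>
    mutate(gene_id = sprintf("g_%s_%03d", .data$chromosome, .data$order_index),
           start = .data$order_index * 10000L,
           end = .data$order_index * 10000L + 2000L)

  gene_at <- function(chr, ord) {
    if (is.numeric(chr)) chr <- sprintf("chr%02d", chr)
    if (any(ord < 1 | ord > genes_per_chr)) abort("planted structure falls off the chromosome")
    sprintf("g_%s_%03d", chr, ord)
  }

  used <- character(0)
  pairs <- tibble(gene_a = character(), gene_b = character(), class = character())
  if (!is.null(tandem_arrays)) {
    tandem_arrays <- as_tibble(tandem_arrays)
    for (i in seq_len(nrow(tandem_arrays))) {
      members <- gene_at(tandem_arrays$chr[i],
                         tandem_arrays$start[i] + seq_len(tandem_arrays$size[i]) - 1L)
      if (any(members %in% used)) abort("overlapping planted structures")
      used <- c(used, members)
      combos <- utils::combn(members, 2)
      pairs <- bind_rows(pairs, tibble(gene_a = combos[1, ], gene_b = combos[2, ],
                                       class = "tandem"))
    }
  }
  if (!is.null(collinear_blocks)) {
    collinear_blocks <- as_tibble(collinear_blocks)
    for (i in seq_len(nrow(collinear_blocks))) {
      len <- collinear_blocks$length[i]
      a <- gene_at(collinear_blocks$chr_a[i], collinear_blocks$start_a[i] + seq_len(len) - 1L)
      b <- gene_at(collinear_blocks$chr_b[i], collinear_blocks$start_b[i] + seq_len(len) - 1L)
      if (any(c(a, b) %in% used)) abort("overlapping planted structures")
      used <- c(used, a, b)
      pairs <- bind_rows(pairs, tibble(gene_a = a, gene_b = b, class = "wgd_segmental"))
    }
  }

  with_seed(seed, {
    gene_map$strand <- sample(c("+", "-"), nrow(gene_map), replace = TRUE)
    if (n_dispersed > 0) {
      if (n_chromosomes < 2) abort("dispersed decoys need at least two chromosomes")
      ord_of <- setNames(gene_map$order_index, gene_map$gene_id)
      chr_of <- setNames(gene_map$chromosome, gene_map$gene_id)
      # existing anchors per canonical chromosome pair; decoys must stay more
      # than one chaining gap away from them (and from each other) so they can
      # never extend or form a collinear chain
      anchor_key <- function(ga, gb) {
        swap <- chr_of[ga] > chr_of[gb]
        tibble(chr_a = ifelse(swap, chr_of[gb], chr_of[ga]),
               chr_b = ifelse(swap, chr_of[ga], chr_of[gb]),
               o_a = ifelse(swap, ord_of[gb], ord_of[ga]),
               o_b = ifelse(swap, ord_of[ga], ord_of[gb]))
      }
      block_anchors <- if (any(pairs$class == "wgd_segmental")) {
        anchor_key(pairs$gene_a[pairs$class == "wgd_segmental"],
                   pairs$gene_b[pairs$class == "wgd_segmental"])
      } else {
        tibble(chr_a = character(), chr_b = character(),
               o_a = integer(), o_b = integer())
      }
      gap <- 25L   # default chaining gap the decoys must stay outside of
      min_anchors <- 5L
      chainable <- function(set, o_a, o_b) {
        d_a <- abs(set$o_a - o_a); d_b <- abs(set$o_b - o_b)
        any(d_a > 0 & d_b > 0 & d_a <= gap & d_b <= gap)
      }
      decoys <- tibble(chr_a = character(), chr_b = character(),
                       o_a = integer(), o_b = integer())
      free <- setdiff(gene_map$gene_id, used)
      disp <- vector("list", n_dispersed)
      for (i in seq_len(n_dispersed)) {
        placed <- FALSE
        for (try in 1:1000) {
          ga <- sample(free, 1)
          avail_b <- free[chr_of[free] != chr_of[ga]]
          if (!base::length(avail_b)) break
          gb <- sample(avail_b, 1)
          cand <- anchor_key(ga, gb)
          same_blk <- block_anchors[block_anchors$chr_a == cand$chr_a &
                                      block_anchors$chr_b == cand$chr_b, ]
          if (nrow(same_blk) && chainable(same_blk, cand$o_a, cand$o_b)) next
          same_dec <- decoys[decoys$chr_a == cand$chr_a &
                               decoys$chr_b == cand$chr_b, ]
          with_cand <- bind_rows(same_dec, cand)
          with_cand <- with_cand[order(with_cand$o_a, with_cand$o_b), ]
          longest <- base::length(
            longest_monotone_chain(with_cand$o_a, with_cand$o_b, gap)$idx)
          if (longest >= min_anchors) next  # decoys must never form a block
          disp[[i]] <- tibble(gene_a = ga, gene_b = gb, class = "dispersed")
          decoys <- bind_rows(decoys, cand)
          free <- setdiff(free, c(ga, gb))
          placed <- TRUE
          break
        }
        if (!placed) abort("could not place dispersed decoys off-structure")
      }
      pairs <- bind_rows(pairs, list_rbind(disp))
    }
    pairs$pair_id <- sprintf("hp%04d", seq_len(nrow(pairs)))
    list(
      gene_map = gene_map |> select("gene_id", "chromosome", "order_index",
                                    "start", "end", "strand"),
      pairs = pairs |> select("pair_id", "gene_a", "gene_b"),
      truth = pairs |> select("pair_id", "class")
    )
  })
}
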