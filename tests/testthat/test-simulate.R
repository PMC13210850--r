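test_that("generators are deterministic under a fixed seed", {
  a <- sim_physiology(4, n_replicates = 2, seed = 11)
  b <- sim_physiology(4, n_replicates = 2, seed = 11)
  expect_identical(a, b)
  expect_false(identical(a, sim_physiology(4, n_replicates = 2, seed = 12)))

  expect_identical(sim_expression_atlas(50, seed = 3), sim_expression_atlas(50, seed = 3))
  expect_identical(sim_cold_timecourse(30, 4, seed = 5), sim_cold_timecourse(30, 4, seed = 5))
  expect_identical(sim_qpcr(seed = 7), sim_qpcr(seed = 7))
  expect_identical(sim_cds_pairs(3, 20, 0.5, 0.2, seed = 9),
                   sim_cds_pairs(3, 20, 0.5, 0.2, seed = 9))
  expect_identical(sim_gene_map(2, 30, n_dispersed = 3, seed = 13),
                   sim_gene_map(2, 30, n_dispersed = 3, seed = 13))
  d <- default_motif_dictionary()
  expect_identical(sim_promoters(3, length = 200, dictionary = d, seed = 15),
                   sim_promoters(3, length = 200, dictionary = d, seed = 15))
})

test_that("noiseless physiology is monotone in latent tolerance", {
  sim <- sim_physiology(2, n_replicates = 1, noise_cv = 0, seed = 1,
                        theta = c(0, 1))
  w <- sim$indicators |>
    dplyr::filter(timepoint > 0) |>
    tidyr::pivot_wider(names_from = cultivar, values_from = value)
  pos <- w |> dplyr::filter(variable != "MDA")
  mda <- w |> dplyr::filter(variable == "MDA")
  expect_true(all(pos$cv02 > pos$cv01))   # tolerant > sensitive for benefits
  expect_true(all(mda$cv02 < mda$cv01))   # and lower membrane damage
})

test_that("physiology table has the full factorial layout", {
  sim <- sim_physiology(14, timepoints = c(0, 1, 3, 5, 7), n_replicates = 5,
                        seed = 2)
  counts <- dplyr::count(sim$indicators, variable)
  expect_setequal(counts$variable, indicator_specs()$variable)
  expect_true(all(counts$n == 14 * 5 * 5))
  expect_error(sim_physiology(2, seed = 1), "n_cultivars")
  expect_error(sim_physiology(5, n_replicates = 0, seed = 1), "n_replicates")
})

test_that("expression atlas plants silent and tissue-specific genes", {
  sim <- sim_expression_atlas(191, n_specific_per_tissue = 10, n_silent = 4,
                              seed = 21)
  mat <- as.matrix(sim$expression[, -1])
  zero_rows <- rownames(mat)[rowSums(mat) == 0] %||%
    sim$expression$gene_id[rowSums(mat) == 0]
  expect_length(sim$expression$gene_id[rowSums(mat) == 0], 4)
  expect_setequal(sim$expression$gene_id[rowSums(mat) == 0], sim$truth$silent_genes)

  tp <- tau_profile(sim$expression)
  planted <- tp |> dplyr::semi_join(sim$truth$specific_genes, by = "gene_id")
  expect_true(all(planted$tau > 0.8))
  got <- planted |> dplyr::left_join(sim$truth$specific_genes, by = "gene_id")
  expect_true(all(got$specific_tissue == got$tissue))

  expect_error(sim_expression_atlas(10, n_specific_per_tissue = 2, n_silent = 4,
                                    seed = 1), "exceed")
})

test_that("zero-leakage specific genes reach tau exactly 1", {
  sim <- sim_expression_atlas(30, n_specific_per_tissue = 2, n_silent = 0,
                              leakage = 0, seed = 4)
  tp <- tau_profile(sim$expression) |>
    dplyr::semi_join(sim$truth$specific_genes, by = "gene_id")
  expect_equal(tp$tau, rep(1, nrow(tp)))
})

test_that("noiseless cold time course plants exact log2 fold changes", {
  sim <- sim_cold_timecourse(20, 5, induction_log2fc = 2, noise_cv = 0, seed = 6)
  scr <- cold_screen(sim$expression)
  planted <- scr |> dplyr::filter(gene_id %in% sim$truth)
  expect_equal(planted$log2fc_12h, rep(2, 5), tolerance = 1e-12)
  # 24 h sits strictly between baseline and peak for induced genes
  expect_true(all(planted$log2fc_24h > 0 & planted$log2fc_24h < 2))
  others <- scr |> dplyr::filter(!gene_id %in% sim$truth)
  expect_equal(others$log2fc_12h, rep(0, nrow(others)), tolerance = 1e-12)
})

test_that("qPCR generator plants folds on the Ct scale", {
  ct <- sim_qpcr(cultivars = "A", true_fold = tibble::tibble(
    cultivar = "A", timepoint = 12, fold = 8), ct_sd = 0, seed = 8)
  m <- ct |> dplyr::filter(role == "target") |>
    dplyr::group_by(timepoint) |> dplyr::summarise(ct = mean(ct))
  expect_equal(m$ct[m$timepoint == 0] - m$ct[m$timepoint == 12], 3)  # log2(8)
  ref <- ct |> dplyr::filter(role == "reference")
  expect_equal(unique(ref$ct), 18)
  expect_error(sim_qpcr(true_fold = tibble::tibble(
    cultivar = "DR-2", timepoint = 12, fold = -1), seed = 1), "positive")
})

test_that("promoter generator records planted positions and strands", {
  d <- default_motif_dictionary()
  plants <- tibble::tibble(promoter_id = c("prom001", "prom001", "prom002"),
                           element = c("ABRE", "G-box", "LTR"),
                           strand = c("+", "-", "-"))
  sim <- sim_promoters(3, length = 500, dictionary = d, plants = plants,
                       seed = 31)
  expect_equal(nrow(sim$truth), 3)
  for (i in seq_len(nrow(sim$truth))) {
    tr <- sim$truth[i, ]
    seq <- sim$promoters$sequence[sim$promoters$promoter_id == tr$promoter_id]
    ins <- substr(seq, tr$start + 1, tr$start + nchar(tr$instance))
    expect_identical(ins, tr$instance)
  }
  # minus-strand instance is the reverse complement of a pattern realization
  mins <- sim$truth[sim$truth$strand == "-", ][1, ]
  pat <- d$pattern[d$element == mins$element]
  expect_identical(nchar(mins$instance), nchar(pat))
})

test_that("codon pair generator honours t = 0 and omega = 0", {
  s0 <- sim_cds_pairs(4, 30, omega = 0.5, t = 0, seed = 41)
  expect_identical(s0$pairs$seq_a, s0$pairs$seq_b)
  est <- kaks_estimate(s0$pairs)
  expect_true(all(est$ka == 0 & est$ks == 0))
  expect_true(all(est$undefined_reason == "Ks=0"))

  sw <- sim_cds_pairs(10, 100, omega = 0, t = 0.3, seed = 42)
  expect_true(all(sw$truth$n_nonsyn == 0))
  expect_true(sum(sw$truth$n_syn) > 0)
})

test_that("gene map generator plants tandem arrays, blocks and decoys", {
  sim <- sim_gene_map(3, 40,
                      tandem_arrays = tibble::tibble(chr = 1, start = 5, size = 3),
                      collinear_blocks = tibble::tibble(chr_a = 2, chr_b = 3,
                                                        start_a = 10, start_b = 20,
                                                        length = 5),
                      n_dispersed = 4, seed = 51)
  expect_equal(sum(sim$truth$class == "tandem"), 3)       # C(3,2)
  expect_equal(sum(sim$truth$class == "wgd_segmental"), 5)
  expect_equal(sum(sim$truth$class == "dispersed"), 4)
  expect_true(all(sim$pairs$gene_a %in% sim$gene_map$gene_id))
  expect_true(all(sim$pairs$gene_b %in% sim$gene_map$gene_id))

  expect_error(sim_gene_map(2, 20,
    tandem_arrays = tibble::tibble(chr = c(1, 1), start = c(3, 4), size = c(3, 3)),
    seed = 1), "overlap")
  expect_error(sim_gene_map(1, 10,
    tandem_arrays = tibble::tibble(chr = 1, start = 9, size = 5), seed = 1),
    "chromosome")
})
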