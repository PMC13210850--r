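test_that("dictionary validation rejects malformed entries", {
  d <- default_motif_dictionary()
  expect_equal(nrow(d), 30)
  expect_setequal(unique(d$class),
                  c("hormone", "stress", "light", "development", "other")[
                    c("hormone", "stress", "light", "development", "other") %in% d$class])
  expect_error(scan_promoters(c(p = "ACGT"), tibble::tibble(
    element = "x", pattern = "ACGT", class = "nonsense")), "classes")
  expect_error(scan_promoters(c(p = "ACGT"), tibble::tibble(
    element = "x", pattern = "AC-GT", class = "stress")), "IUPAC")
  expect_error(scan_promoters(c(p = "ACGT"), tibble::tibble(
    element = c("x", "x"), pattern = c("AAA", "CCC"),
    class = c("stress", "light"))), "exactly one class")
})

test_that("planted plus-strand element is found at its position", {
  hits <- scan_promoters(c(p1 = "AAAACGTGAAA"), tibble::tibble(
    element = "ABRE", pattern = "ACGTG", class = "hormone"))
  plus <- hits[hits$strand == "+", ]
  expect_equal(nrow(plus), 1)
  expect_equal(plus$start, 3L)  # 0-based
})

test_that("palindromic patterns hit once per strand at the same position", {
  hits <- scan_promoters(c(p1 = "TTCACGTGTT"), tibble::tibble(
    element = "G-box", pattern = "CACGTG", class = "light"))
  expect_equal(nrow(hits), 2)
  expect_setequal(hits$strand, c("+", "-"))
  expect_equal(unique(hits$start), 2L)
})

test_that("empty dictionaries, invalid characters and N are handled", {
  empty <- scan_promoters(c(p1 = "ACGTACGT"), tibble::tibble(
    element = character(), pattern = character(), class = character()))
  expect_equal(nrow(empty), 0)
  expect_error(scan_promoters(c(p1 = "ACGU"), tibble::tibble(
    element = "x", pattern = "ACG", class = "other")), "A, C, G, T, N")
  withN <- scan_promoters(c(p1 = "ACNTG"), tibble::tibble(
    element = "x", pattern = "ACGTG", class = "other"))
  expect_equal(nrow(withN), 0)  # N never matches
})

test_that("scan matches the naive sliding-window oracle on random promoters", {
  d <- default_motif_dictionary()
  set.seed(11)
  proms <- vapply(1:12, function(i) paste(sample(c("A", "C", "G", "T"), 400,
                                                 replace = TRUE), collapse = ""),
                  character(1))
  names(proms) <- sprintf("p%02d", 1:12)
  hits <- scan_promoters(proms, d)
  for (pid in names(proms)) {
    for (k in seq_len(nrow(d))) {
      exp_plus <- oracle_scan(proms[[pid]], d$pattern[k])
      exp_minus <- oracle_scan(proms[[pid]], oracle_revcomp(d$pattern[k]))
      got <- hits[hits$promoter_id == pid & hits$element == d$element[k], ]
      expect_equal(sort(got$start[got$strand == "+"]), sort(exp_plus),
                   ignore_attr = TRUE)
      expect_equal(sort(got$start[got$strand == "-"]), sort(exp_minus),
                   ignore_attr = TRUE)
    }
  }
})

test_that("strand symmetry: reverse-complementing promoters preserves totals", {
  d <- default_motif_dictionary()
  set.seed(13)
  proms <- vapply(1:6, function(i) paste(sample(c("A", "C", "G", "T"), 300,
                                                replace = TRUE), collapse = ""),
                  character(1))
  names(proms) <- sprintf("p%d", 1:6)
  rc <- vapply(proms, coldtol:::revcomp, character(1))
  t1 <- scan_promoters(proms, d) |> dplyr::count(element)
  t2 <- scan_promoters(rc, d) |> dplyr::count(element)
  expect_equal(t1, t2)
})

test_that("per-element totals are additive over promoter sets", {
  d <- default_motif_dictionary()
  set.seed(17)
  mk <- function(n, len) {
    out <- vapply(seq_len(n), function(i) paste(sample(c("A", "C", "G", "T"), len,
                                                       replace = TRUE), collapse = ""),
                  character(1))
    names(out) <- paste0("s", seq_len(n), "_", len)
    out
  }
  s1 <- mk(4, 250); s2 <- mk(4, 350)
  tot <- function(h) h |> dplyr::count(element, name = "total")
  combined <- tot(scan_promoters(c(s1, s2), d))
  sep <- dplyr::bind_rows(scan_promoters(s1, d), scan_promoters(s2, d)) |> tot()
  expect_equal(combined, sep)
})

test_that("summaries report class totals and the joint-presence fraction", {
  d <- tibble::tibble(element = c("h1", "s1", "l1"),
                      pattern = c("ACGTGC", "CCGAAA", "GGTTAA"),
                      class = c("hormone", "stress", "light"))
  proms <- c(all3 = paste0("ACGTGC", "CCGAAA", "GGTTAA", strrep("A", 20)),
             only_h = paste0("ACGTGC", strrep("A", 30)),
             none = strrep("T", 40))
  hits <- scan_promoters(proms, d)
  sm <- summarize_elements(hits, proms)
  expect_equal(sm$joint$n_with, 1)
  expect_equal(sm$joint$percentage, 100 / 3)
  sm_any <- summarize_elements(hits, proms, joint_mode = "any")
  expect_equal(sm_any$n_with %||% sm_any$joint$n_with, 2)
  ec <- element_counts(hits, proms)
  expect_true(all(c("all3", "only_h", "none") %in% ec$per_class$promoter_id))
})

test_that("generator plants are recovered exactly, including minus strand", {
  d <- default_motif_dictionary()
  plants <- tibble::tibble(
    promoter_id = rep(sprintf("prom%03d", 1:5), each = 2),
    element = rep(c("ABRE", "LTR"), 5),
    strand = rep(c("+", "-"), 5))
  sim <- sim_promoters(5, length = 600, dictionary = d, plants = plants,
                       scrub_background = TRUE, seed = 19)
  hits <- scan_promoters(sim$promoters, d)
  # every planted instance is found at its recorded position and strand
  found <- dplyr::semi_join(sim$truth, hits,
                            by = c("promoter_id", "element", "start", "strand"))
  expect_equal(nrow(found), nrow(sim$truth))
  # scrubbed background: no hits beyond plants except overlaps with plants
  extra <- dplyr::anti_join(hits, sim$truth,
                            by = c("promoter_id", "element", "start", "strand"))
  if (nrow(extra)) {
    widths <- nchar(d$pattern[match(extra$element, d$element)])
    overlaps <- vapply(seq_len(nrow(extra)), function(i) {
      tr <- sim$truth[sim$truth$promoter_id == extra$promoter_id[i], ]
      any(extra$start[i] < tr$start + nchar(tr$instance) &
            extra$start[i] + widths[i] > tr$start)
    }, logical(1))
    expect_true(all(overlaps))
  }
})

test_that("promoter extraction respects strand and clips at contig edges", {
  genome <- c(chr1 = paste0(strrep("A", 10), "CCGGTT", strrep("G", 10)))
  map <- tibble::tibble(gene_id = c("gp", "gm", "edge"),
                        chromosome = "chr1",
                        start = c(11, 3, 1), end = c(16, 8, 2),
                        strand = c("+", "-", "+"))
  pr <- extract_promoters(genome, map, upstream = 4)
  expect_equal(pr$sequence[pr$promoter_id == "gp"], "AAAA")      # bases 7-10
  # minus strand: bases 9-12 downstream of end, reverse complemented
  expect_equal(pr$sequence[pr$promoter_id == "gm"], substr(genome, 9, 12) |>
                 coldtol:::revcomp())
  expect_equal(pr$sequence[pr$promoter_id == "edge"], "")        # clipped away
})
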