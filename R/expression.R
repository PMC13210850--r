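#' Tau tissue-specificity index of one expression profile
#'
#' tau = sum(1 - x_i / max(x)) / (n - 1) over per-tissue mean abundances:
#' 0 for perfectly uniform expression, 1 for single-tissue expression.
#' Undefined (NA) when the gene is silent in every tissue.
#'
#' @param x non-negative per-tissue abundances (replicates already averaged).
#' @return tau in \[0, 1\], or NA when max(x) == 0.
#' @examples
#' tau_index(c(8, 2, 2, 2, 2, 2))  # 0.75
#' @export
tau_index <- function(x) {
  if (any(x < 0)) abort("negative abundance")
  if (base::length(x) < 2) abort("tau needs at least two tissues")
  m <- max(x)
  if (m == 0) return(NA_real_)
  sum(1 - x / m) / (base::length(x) - 1)
}

#' Tau profile and specificity classification for an expression atlas
#'
#' Computes tau per gene and classifies: tissue-specific when tau > 0.8
#' (strict), with the top tissue reported; ubiquitous when tau < 0.2;
#' not expressed when the gene is silent everywhere; intermediate otherwise.
#'
#' @param expression wide tibble: gene_id plus one numeric column per
#'   tissue (replicates already averaged).
#' @param threshold_specific,threshold_ubiquitous classification cut-offs.
#' @return tibble: gene_id, tau, category, specific_tissue (NA unless
#'   specific).
#' @export
tau_profile <- function(expression,
                        threshold_specific = 0.8,
                        threshold_ubiquitous = 0.2) {
  tissues <- names(expression)[vapply(expression, is.numeric, logical(1))]
  if (base::length(tissues) < 2) abort("need at least two tissue columns")
  mat <- as.matrix(expression[, tissues])
  tau <- apply(mat, 1, tau_index)
  top <- tissues[max.col(mat, ties.method = "first")]
  category <- dplyr::case_when(
    is.na(tau) ~ "not_expressed",
    tau > threshold_specific ~ "specific",
    tau < threshold_ubiquitous ~ "ubiquitous",
    TRUE ~ "intermediate"
  )
  tibble(
    gene_id = expression$gene_id %||% as.character(seq_len(nrow(mat))),
    tau = tau,
    category = category,
    specific_tissue = ifelse(category == "specific", top, NA_character_)
  )
}

#' Per-tissue counts of tissue-specific genes
#'
#' @param tau_results output of [tau_profile()].
#' @return tibble: tissue, n_specific.
#' @export
specificity_counts <- function(tau_results) {
  tau_results |>
    filter(.data$category == "specific") |>
    count(tissue = .data$specific_tissue, name = "n_specific") |>
    arrange(dplyr::desc(.data$n_specific))
}

#' Fraction of genes expressed in at least one condition
#'
#' @param expression wide tibble: gene_id plus numeric condition columns.
#' @param min_abundance a gene counts as expressed when any condition
#'   exceeds this (default 0, i.e. any detectable signal).
#' @return tibble: n_expressed, n_total, percentage.
#' @export
expressed_fraction <- function(expression, min_abundance = 0) {
  cols <- names(expression)[vapply(expression, is.numeric, logical(1))]
  if (!base::length(cols) || !nrow(expression)) abort("empty expression matrix")
  mat <- as.matrix(expression[, cols])
  expressed <- apply(mat, 1, function(r) any(r > min_abundance))
  tibble(
    n_expressed = sum(expressed),
    n_total = nrow(mat),
    percentage = 100 * sum(expressed) / nrow(mat)
  )
}

#' Log2 fold change between two replicate groups
#'
#' log2((mean(treated) + pseudocount) / (mean(baseline) + pseudocount));
#' the pseudocount guards against zero means on TPM-like scales.
#'
#' @param treated,baseline non-negative replicate abundances.
#' @param pseudocount positive stabilizer (default 1).
#' @return a single log2 fold change.
#' @export
log2_fold_change <- function(treated, baseline, pseudocount = 1) {
  if (pseudocount <= 0) abort("pseudocount must be positive")
  if (any(treated < 0) || any(baseline < 0)) abort("negative abundance")
  log2((mean(treated) + pseudocount) / (mean(baseline) + pseudocount))
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' @param p raw p-values in \[0, 1\].
#' @return adjusted values in the input order.
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values outside [0, 1]")
  p.adjust(p, method = "BH")
}

#' Cold-induction screen on a replicated time course
#'
#' Per gene: log2 fold change at the peak timepoint (12 h) versus baseline
#' (0 h) on pseudocounted means; a two-sided two-sample t comparison of
#' log2(x + pseudocount) replicate values; BH adjustment across genes.
#' The default pools the variance across the two timepoints: under a
#' multiplicative noise model the log-scale variance is homogeneous, and
#' with the usual three replicates the Welch degrees-of-freedom
#' approximation collapses to ~2 and sacrifices most of the power, so the
#' pooled test is the default and `test = "welch"` is available when
#' heteroscedasticity is a real concern.
#' A gene is induced when log2FC >= `lfc_threshold` and FDR <
#' `fdr_threshold`, and strongly induced when additionally log2FC >=
#' `strong_threshold`.
#'
#' @param timecourse long tibble (gene_id, timepoint, replicate, value) as
#'   produced by [sim_cold_timecourse()], with at least two replicates per
#'   timepoint.
#' @param baseline,peak timepoints compared (defaults 0 and 12 h);
#'   `extra` names a further timepoint whose log2FC is reported (24 h).
#' @param lfc_threshold,fdr_threshold,strong_threshold screen thresholds
#'   (defaults 1, 0.05, 2).
#' @param pseudocount stabilizer for fold changes and log transforms.
#' @param test "pooled" (two-sample t with pooled variance, the default) or
#'   "welch" (unequal-variance).
#' @param p_values optional externally computed p-values (named by gene);
#'   when supplied the internal test is skipped.
#' @return tibble of class `cold_screen`, sorted by FDR then |log2FC|:
#'   gene_id, log2fc_12h, log2fc_24h, p_value, fdr, induced,
#'   strongly_induced.
#' @export
cold_screen <- function(timecourse,
                        baseline = 0,
                        peak = 12,
                        extra = 24,
                        lfc_threshold = 1,
                        fdr_threshold = 0.05,
                        strong_threshold = 2,
                        pseudocount = 1,
                        test = c("pooled", "welch"),
                        p_values = NULL) {
  test <- match.arg(test)
  need <- c("gene_id", "timepoint", "value")
  if (!all(need %in% names(timecourse))) {
    abort(sprintf("time course needs columns: %s", paste(need, collapse = ", ")))
  }
  tps <- unique(timecourse$timepoint)
  for (tp in c(baseline, peak)) {
    if (!tp %in% tps) abort(sprintf("missing timepoint %s", format(tp)))
  }
  have_extra <- !is.null(extra) && extra %in% tps

  per_gene <- timecourse |>
    filter(.data$timepoint %in% c(baseline, peak, if (have_extra) extra)) |>
    group_by(.data$gene_id) |>
    summarise(
      log2fc_12h = log2_fold_change(.data$value[.data$timepoint == peak],
                                    .data$value[.data$timepoint == baseline],
                                    pseudocount),
      log2fc_24h = if (have_extra) {
        log2_fold_change(.data$value[.data$timepoint == extra],
                         .data$value[.data$timepoint == baseline],
                         pseudocount)
      } else NA_real_,
      p_value = two_sample_log_p(.data$value[.data$timepoint == peak],
                                 .data$value[.data$timepoint == baseline],
                                 pseudocount, test),
      .groups = "drop"
    )
  if (!is.null(p_values)) {
    per_gene$p_value <- unname(p_values[per_gene$gene_id])
  }
  per_gene <- per_gene |>
    mutate(
      fdr = bh_fdr(.data$p_value),
      induced = .data$log2fc_12h >= lfc_threshold & .data$fdr < fdr_threshold,
      strongly_induced = .data$induced & .data$log2fc_12h >= strong_threshold
    ) |>
    arrange(.data$fdr, dplyr::desc(abs(.data$log2fc_12h)))
  class(per_gene) <- c("cold_screen", class(per_gene))
  per_gene
}

# two-sided t on log2(x + pseudocount); constant groups degrade to p = 1
# (no difference) or ~0 (deterministic difference)
two_sample_log_p <- function(a, b, pseudocount, test = "pooled") {
  la <- log2(a + pseudocount)
  lb <- log2(b + pseudocount)
  if (base::length(la) < 2 || base::length(lb) < 2) {
    abort("need at least two replicates per timepoint")
  }
  if (sd(la) < 1e-12 && sd(lb) < 1e-12) {
    return(if (abs(mean(la) - mean(lb)) < 1e-12) 1 else 1e-300)
  }
  tryCatch(t.test(la, lb, var.equal = (test == "pooled"))$p.value,
           error = function(e) 1)
}
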