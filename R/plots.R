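#' Plot per-cultivar D values from a tolerance fit
#'
#' Bar chart of comprehensive cold-tolerance scores, coloured by tolerance
#' class, with the 0.40 and 0.70 classification thresholds drawn.
#'
#' @param object a `tolerance_fit`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot tolerance_fit
#' @export
autoplot.tolerance_fit <- function(object, ...) {
  df <- object$scores |>
    mutate(cultivar = factor(.data$cultivar, levels = .data$cultivar))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cultivar, y = .data$d_value,
                                   fill = .data$tolerance_class)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = c(0.40, 0.70), linetype = "dashed",
                        colour = "grey40") +
    ggplot2::scale_fill_manual(values = c(strong = "#2166ac",
                                          moderate = "#92c5de",
                                          weak = "#d6604d")) +
    ggplot2::labs(x = NULL, y = "comprehensive cold-tolerance value D",
                  fill = "class") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Volcano-style plot of a cold-induction screen
#'
#' @param object a `cold_screen` tibble.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot cold_screen
#' @export
autoplot.cold_screen <- function(object, ...) {
  df <- as_tibble(object) |>
    mutate(status = dplyr::case_when(.data$strongly_induced ~ "strongly induced",
                                     .data$induced ~ "induced",
                                     TRUE ~ "not induced"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2fc_12h,
                                   y = -log10(pmax(.data$fdr, 1e-300)),
                                   colour = .data$status)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_vline(xintercept = c(1, 2), linetype = "dashed",
                        colour = "grey40") +
    ggplot2::scale_colour_manual(values = c("strongly induced" = "#b2182b",
                                            "induced" = "#ef8a62",
                                            "not induced" = "grey60")) +
    ggplot2::labs(x = "log2 fold change (12 h vs 0 h)", y = "-log10 FDR",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Histogram of tau tissue-specificity values
#'
#' @param tau_results output of [tau_profile()].
#' @param threshold_specific,threshold_ubiquitous thresholds drawn as
#'   reference lines.
#' @return a ggplot.
#' @export
plot_tau_distribution <- function(tau_results, threshold_specific = 0.8,
                                  threshold_ubiquitous = 0.2) {
  df <- tau_results |> filter(!is.na(.data$tau))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$tau)) +
    ggplot2::geom_histogram(bins = 40, fill = "#4393c3", colour = "white") +
    ggplot2::geom_vline(xintercept = c(threshold_ubiquitous, threshold_specific),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = expression(tau ~ "tissue-specificity index"),
                  y = "genes") +
    ggplot2::theme_minimal()
}

#' Box plot of relative expression with significance letters
#'
#' @param rel [relative_expression()] output filtered to one gene and
#'   timepoint, or any tibble with `cultivar` and `fold`.
#' @param kd matching [kruskal_dunn()] result supplying the letters.
#' @return a ggplot.
#' @export
plot_fold_letters <- function(rel, kd) {
  lettered <- kd$letters |> rename(cultivar = "group")
  top <- rel |> group_by(.data$cultivar) |>
    summarise(y = max(.data$fold) * 1.08, .groups = "drop") |>
    left_join(lettered, by = "cultivar")
  ggplot2::ggplot(rel, ggplot2::aes(x = .data$cultivar, y = .data$fold)) +
    ggplot2::geom_boxplot(fill = "#d1e5f0") +
    ggplot2::geom_text(data = top, ggplot2::aes(y = .data$y, label = .data$letter)) +
    ggplot2::labs(x = NULL, y = expression(2^{-Delta * Delta * Ct} ~ "fold")) +
    ggplot2::theme_minimal()
}
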