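#' Average technical replicates on the Ct scale
#'
#' @param ct_table tibble with columns cultivar, timepoint, gene, role,
#'   bio_rep, tech_rep, ct (see [sim_qpcr()]).
#' @return tibble with one arithmetic-mean Ct per biological replicate.
#' @export
collapse_technical <- function(ct_table) {
  need <- c("cultivar", "timepoint", "gene", "role", "bio_rep", "ct")
  if (!all(need %in% names(ct_table))) {
    abort(sprintf("Ct table needs columns: %s", paste(need, collapse = ", ")))
  }
  ct_table |>
    group_by(.data$cultivar, .data$timepoint, .data$gene, .data$role, .data$bio_rep) |>
    summarise(ct = mean(.data$ct), .groups = "drop")
}

#' 2^-ddCt relative expression
#'
#' Technical replicates are averaged on the Ct scale; per biological
#' replicate dCt = Ct_target - Ct_reference within the same cultivar,
#' timepoint and replicate; ddCt subtracts the mean dCt of the calibrator
#' condition (same cultivar and target gene); fold = 2^-ddCt, so the mean
#' calibrator fold is 1 by construction. Amplification efficiency is fixed
#' at 2 (no efficiency correction).
#'
#' @param ct_table Ct tibble as in [collapse_technical()].
#' @param calibrator calibrator timepoint (default 0, the pre-treatment
#'   sample of the same cultivar — the conventional time-course choice).
#' @return tibble: cultivar, gene, timepoint, bio_rep, delta_ct, ddct, fold.
#' @examples
#' ct <- sim_qpcr(true_fold = tibble::tibble(cultivar = "DR-2",
#'   timepoint = 12, fold = 8), ct_sd = 0, seed = 1)
#' relative_expression(ct)
#' @export
relative_expression <- function(ct_table, calibrator = 0) {
  ct <- collapse_technical(ct_table)
  ref <- ct |> filter(.data$role == "reference") |>
    select("cultivar", "timepoint", "bio_rep", ref_ct = "ct")
  tgt <- ct |> filter(.data$role == "target")
  if (!nrow(tgt) || !nrow(ref)) abort("Ct table needs both target and reference rows")
  joined <- left_join(tgt, ref, by = c("cultivar", "timepoint", "bio_rep"))
  if (anyNA(joined$ref_ct)) abort("missing reference measurement for some samples")
  joined <- joined |> mutate(delta_ct = .data$ct - .data$ref_ct)
  cal <- joined |>
    filter(.data$timepoint == calibrator) |>
    group_by(.data$cultivar, .data$gene) |>
    summarise(cal_dct = mean(.data$delta_ct), .groups = "drop")
  if (!nrow(cal)) abort(sprintf("calibrator condition %s absent", format(calibrator)))
  out <- joined |>
    left_join(cal, by = c("cultivar", "gene"))
  if (anyNA(out$cal_dct)) abort("calibrator condition absent for some cultivar/gene")
  out |>
    mutate(ddct = .data$delta_ct - .data$cal_dct, fold = 2^(-.data$ddct)) |>
    select("cultivar", "gene", "timepoint", "bio_rep", "delta_ct", "ddct", "fold")
}

#' Ratio of relative expression between two cultivars
#'
#' Compares the mean 2^-ddCt fold of cultivar `a` to cultivar `b` for one
#' gene at one timepoint (ratio of mean folds by default; the
#' fold-of-means alternative divides before averaging is impossible here,
#' so it exponentiates the difference of mean ddCt instead).
#'
#' @param rel output of [relative_expression()].
#' @param gene,timepoint condition selected.
#' @param cultivar_a,cultivar_b numerator and denominator cultivars.
#' @param method "mean_fold" (default) or "geometric" (ratio of geometric
#'   mean folds, i.e. difference of mean ddCt).
#' @return tibble: ratio, mean_a, mean_b, sd_a, sd_b, n_a, n_b.
#' @export
fold_ratio <- function(rel, gene, timepoint, cultivar_a, cultivar_b,
                       method = c("mean_fold", "geometric")) {
  method <- match.arg(method)
  pick <- function(cv) {
    x <- rel |> filter(.data$gene == !!gene, .data$timepoint == !!timepoint,
                       .data$cultivar == cv)
    if (!nrow(x)) abort(sprintf("cultivar '%s' not measured at timepoint %s", cv,
                                format(timepoint)))
    x$fold
  }
  fa <- pick(cultivar_a)
  fb <- pick(cultivar_b)
  ma <- if (method == "mean_fold") mean(fa) else exp(mean(log(fa)))
  mb <- if (method == "mean_fold") mean(fb) else exp(mean(log(fb)))
  if (mb == 0) abort("zero denominator fold")
  tibble(ratio = ma / mb, mean_a = ma, mean_b = mb,
         sd_a = sd(fa), sd_b = sd(fb),
         n_a = base::length(fa), n_b = base::length(fb))
}

#' Kruskal-Wallis omnibus with Dunn post hoc and compact letter display
#'
#' Runs the tie-corrected Kruskal-Wallis test across groups, Dunn
#' z-statistics on mean ranks for every pair with Bonferroni adjustment
#' (multiplication by the number of pairs), and assigns letters by the
#' insert-and-absorb algorithm so that groups sharing a letter are not
#' significantly different at `alpha`.
#'
#' @param data tibble with the response and grouping columns.
#' @param value,group column names (strings) of the response and grouping
#'   factor.
#' @param alpha significance level for the letters (default 0.05).
#' @param p_method "auto" (exact permutation enumeration of the omnibus p
#'   when the total sample size is at most 10, otherwise the chi-squared
#'   approximation), "exact" or "asymptotic". qPCR designs with three
#'   replicates per group are far below chi-squared territory, hence the
#'   exact default at small n.
#' @return object of class `kruskal_dunn` with elements `omnibus`
#'   (statistic, df, p_value), `pairwise` (group1, group2, z, p_value,
#'   p_adjusted) and `letters` (group, mean_rank, letter). [tidy()] returns
#'   the pairwise table; [glance()] the omnibus row.
#' @export
kruskal_dunn <- function(data, value = "fold", group = "cultivar", alpha = 0.05,
                         p_method = c("auto", "exact", "asymptotic")) {
  p_method <- match.arg(p_method)
  x <- data[[value]]
  g <- factor(data[[group]])
  if (nlevels(g) < 2) abort("need at least two groups")
  if (any(table(g) < 2)) abort("need at least two observations per group")
  use_exact <- p_method == "exact" ||
    (p_method == "auto" && base::length(x) <= 10)

  if (max(x) == min(x)) {
    omnibus <- tibble(statistic = 0, df = nlevels(g) - 1L, p_value = 1)
  } else {
    kw <- kruskal.test(x, g)
    p_val <- if (use_exact) kw_exact_p(x, g) else kw$p.value
    omnibus <- tibble(statistic = unname(kw$statistic),
                      df = unname(kw$parameter),
                      p_value = p_val)
  }

  N <- base::length(x)
  r <- rank(x)
  mean_ranks <- tapply(r, g, mean)
  n_g <- tapply(r, g, base::length)
  ties <- table(x)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  lv <- levels(g)
  combos <- utils::combn(lv, 2)
  n_pairs <- ncol(combos)
  pw <- map(seq_len(n_pairs), function(i) {
    a <- combos[1, i]; b <- combos[2, i]
    se <- sqrt((N * (N + 1) / 12 - tie_corr) * (1 / n_g[a] + 1 / n_g[b]))
    z <- if (se == 0) 0 else (mean_ranks[a] - mean_ranks[b]) / se
    p <- 2 * pnorm(-abs(z))
    tibble(group1 = a, group2 = b, z = unname(z), p_value = unname(p),
           p_adjusted = min(1, unname(p) * n_pairs))
  }) |> list_rbind()

  letters_tbl <- cld_insert_absorb(lv[order(mean_ranks, decreasing = TRUE)],
                                   pw, alpha) |>
    left_join(tibble(group = lv, mean_rank = unname(mean_ranks[lv])), by = "group") |>
    select("group", "mean_rank", "letter") |>
    arrange(dplyr::desc(.data$mean_rank))

  structure(list(omnibus = omnibus, pairwise = pw, letters = letters_tbl,
                 alpha = alpha),
            class = "kruskal_dunn")
}

# exact Kruskal-Wallis permutation p: enumerate every distinct assignment of
# the observed ranks to the group sizes and count tie-corrected H statistics
# at least as large as the observed one
kw_exact_p <- function(x, g) {
  r <- rank(x)
  sizes <- as.integer(table(g))
  ties <- table(x)
  tie_div <- 1 - sum(ties^3 - ties) / (base::length(x)^3 - base::length(x))
  h_stat <- function(assign_list) {
    N <- base::length(x)
    h <- 12 / (N * (N + 1)) *
      sum(vapply(assign_list, function(rr) sum(rr)^2 / base::length(rr), numeric(1))) -
      3 * (N + 1)
    if (tie_div > 0) h / tie_div else 0
  }
  obs <- h_stat(split(r, g))
  count <- 0L; total <- 0L
  recurse <- function(remaining, k, acc) {
    if (k == base::length(sizes)) {
      h <- h_stat(c(acc, list(remaining)))
      total <<- total + 1L
      if (h >= obs - 1e-9) count <<- count + 1L
      return(invisible())
    }
    picks <- utils::combn(seq_along(remaining), sizes[k], simplify = FALSE)
    for (p in picks) {
      recurse(remaining[-p], k + 1L, c(acc, list(remaining[p])))
    }
  }
  recurse(r, 1L, list())
  count / total
}

# insert-and-absorb compact letter display: start with one column holding all
# groups; each significant pair splits every column containing both; subset
# columns are absorbed; letters follow column order
cld_insert_absorb <- function(groups_ordered, pairwise, alpha) {
  cols <- list(groups_ordered)
  sig <- pairwise[pairwise$p_adjusted < alpha, , drop = FALSE]
  for (i in seq_len(nrow(sig))) {
    a <- sig$group1[i]; b <- sig$group2[i]
    new_cols <- list()
    for (col in cols) {
      if (all(c(a, b) %in% col)) {
        new_cols <- c(new_cols, list(setdiff(col, a)), list(setdiff(col, b)))
      } else {
        new_cols <- c(new_cols, list(col))
      }
    }
    # absorb columns that are subsets of another
    keep <- rep(TRUE, base::length(new_cols))
    for (j in seq_along(new_cols)) {
      for (l in seq_along(new_cols)) {
        if (j != l && keep[l] &&
            all(new_cols[[j]] %in% new_cols[[l]]) &&
            (base::length(new_cols[[j]]) < base::length(new_cols[[l]]) || j > l)) {
          keep[j] <- FALSE
          break
        }
      }
    }
    cols <- new_cols[keep]
  }
  # order columns by the position of their first (highest-ranked) member
  first_pos <- vapply(cols, function(col) min(match(col, groups_ordered)), numeric(1))
  cols <- cols[order(first_pos)]
  lab <- letters[seq_along(cols)]
  tibble(group = groups_ordered) |>
    mutate(letter = vapply(.data$group, function(gr) {
      paste(lab[vapply(cols, function(col) gr %in% col, logical(1))], collapse = "")
    }, character(1)))
}

#' @method tidy kruskal_dunn
#' @export
tidy.kruskal_dunn <- function(x, ...) x$pairwise

#' @method glance kruskal_dunn
#' @export
glance.kruskal_dunn <- function(x, ...) x$omnibus

#' @export
print.kruskal_dunn <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis chi-squared = %.4g, df = %d, p = %.4g\n",
              x$omnibus$statistic, x$omnibus$df, x$omnibus$p_value))
  cat(sprintf("Dunn pairwise comparisons (Bonferroni), letters at alpha = %g:\n",
              x$alpha))
  print(x$letters, ...)
  invisible(x)
}
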