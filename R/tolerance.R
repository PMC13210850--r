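#' Membership-function (min-max) standardization of a single value
#'
#' The membership function U(X) = (X - Xmin) / (Xmax - Xmin) maps an
#' indicator onto \[0, 1\]; it is the standardization step applied both to
#' the raw physiological indicators and to the composite-indicator scores
#' before they are combined into the D value.
#'
#' @param x value(s) to standardize, within \[x_min, x_max\].
#' @param x_min,x_max range of the indicator across cultivars; `x_max` must
#'   exceed `x_min`.
#' @return value(s) in \[0, 1\].
#' @examples
#' membership(5, 0, 10)
#' @export
membership <- function(x, x_min, x_max) {
  if (!is.numeric(x) || !is.numeric(x_min) || !is.numeric(x_max)) {
    abort("membership() needs numeric inputs")
  }
  if (x_max <= x_min) {
    abort("degenerate range: x_max must be strictly greater than x_min")
  }
  if (any(x < x_min - 1e-12) || any(x > x_max + 1e-12)) {
    abort("x outside [x_min, x_max]")
  }
  pmin(1, pmax(0, (x - x_min) / (x_max - x_min)))
}

#' Collapse a long indicator table to one value per cultivar and variable
#'
#' The scoring pipeline needs a cultivar x variable matrix; measurements are
#' taken over timepoints and replicates, so they must be aggregated first.
#' The default averages replicate means over the stress timepoints (day 0,
#' the unstressed baseline, is excluded); alternatives are a single day or
#' the stress/baseline ratio.
#'
#' @param indicators long tibble (cultivar, variable, timepoint, replicate,
#'   value).
#' @param method "stress_mean" (default), "day" or "ratio".
#' @param day timepoint used when `method = "day"`.
#' @return wide tibble: cultivar plus one column per variable.
#' @export
aggregate_indicators <- function(indicators,
                                 method = c("stress_mean", "day", "ratio"),
                                 day = NULL) {
  method <- match.arg(method)
  need <- c("cultivar", "variable", "timepoint", "value")
  if (!all(need %in% names(indicators))) {
    abort(sprintf("indicator table needs columns: %s", paste(need, collapse = ", ")))
  }
  per_tp <- indicators |>
    group_by(.data$cultivar, .data$variable, .data$timepoint) |>
    summarise(value = mean(.data$value), .groups = "drop")
  agg <- switch(method,
    stress_mean = per_tp |>
      filter(.data$timepoint > min(.data$timepoint)) |>
      group_by(.data$cultivar, .data$variable) |>
      summarise(value = mean(.data$value), .groups = "drop"),
    day = {
      if (is.null(day)) abort("method = 'day' needs `day`")
      per_tp |> filter(.data$timepoint == day) |>
        select("cultivar", "variable", "value")
    },
    ratio = per_tp |>
      group_by(.data$cultivar, .data$variable) |>
      summarise(
        value = mean(.data$value[.data$timepoint > min(.data$timepoint)]) /
          .data$value[.data$timepoint == min(.data$timepoint)],
        .groups = "drop"
      )
  )
  tidyr::pivot_wider(agg, names_from = "variable", values_from = "value")
}

#' Membership-standardize every indicator column of a cultivar table
#'
#' Applies the membership function column-wise, so each variable spans
#' exactly \[0, 1\] with its minimum cultivar at 0 and maximum at 1.
#'
#' @param indicators wide tibble: cultivar column plus numeric variables.
#' @return tibble of the same shape with standardized columns.
#' @export
standardize_indicators <- function(indicators) {
  num <- names(indicators)[vapply(indicators, is.numeric, logical(1))]
  if (!base::length(num)) abort("no numeric indicator columns found")
  if (nrow(indicators) < 2) abort("degenerate range: need at least two cultivars")
  out <- indicators
  for (v in num) {
    x <- indicators[[v]]
    if (anyNA(x)) abort(sprintf("missing values in variable '%s'", v))
    if (max(x) <= min(x)) {
      abort(sprintf("degenerate range in variable '%s' (max == min)", v))
    }
    out[[v]] <- membership(x, min(x), max(x))
  }
  out
}

#' Comprehensive cold-tolerance scoring (membership function + PCA weights)
#'
#' Implements the full composite evaluation: indicator columns are
#' membership-standardized; covariance PCA turns them into composite
#' indicators; the components whose cumulative variance contribution first
#' exceeds `threshold` are retained; each retained component is weighted by
#' its contribution rate; component scores are membership-standardized
#' across cultivars and combined as D = sum U_j * W_j. D lies in \[0, 1\]
#' and larger D means stronger cold tolerance.
#'
#' Eigenvector signs are arbitrary, so each component is oriented so that
#' its direction-weighted loading sum (benefit variables +, cost variables
#' such as MDA -) is non-negative; this pins "larger score = more tolerant".
#'
#' @param indicators either a long table (cultivar, variable, timepoint,
#'   replicate, value), aggregated via [aggregate_indicators()], or a wide
#'   cultivar x variable table.
#' @param directions named vector of +1/-1 per variable; defaults to -1 for
#'   MDA and +1 otherwise.
#' @param threshold cumulative contribution cut-off for component retention
#'   (strictly greater than; default 0.85).
#' @param agg_method,agg_day passed to [aggregate_indicators()] for long
#'   input.
#' @return an object of class `tolerance_fit`: use [tidy()] for per-cultivar
#'   D values and classes, [glance()] for fit-level summaries, and
#'   [autoplot()] to plot.
#' @examples
#' sim <- sim_physiology(n_cultivars = 6, n_replicates = 3, seed = 7)
#' fit <- score_tolerance(sim$indicators)
#' tidy(fit)
#' @export
score_tolerance <- function(indicators,
                            directions = NULL,
                            threshold = 0.85,
                            agg_method = "stress_mean",
                            agg_day = NULL) {
  threshold <- check_fraction(threshold, "threshold", min = 0, max = 1)
  if (all(c("timepoint", "value") %in% names(indicators))) {
    wide <- aggregate_indicators(indicators, method = agg_method, day = agg_day)
  } else {
    wide <- as_tibble(indicators)
  }
  id_col <- if ("cultivar" %in% names(wide)) "cultivar" else names(wide)[1]
  vars <- setdiff(names(wide)[vapply(wide, is.numeric, logical(1))], id_col)
  if (base::length(vars) < 2) abort("need at least two indicator variables")
  if (nrow(wide) < 2) abort("need at least two cultivars")

  if (is.null(directions)) {
    directions <- setNames(ifelse(grepl("mda", vars, ignore.case = TRUE), -1, 1), vars)
  }
  if (!all(vars %in% names(directions))) {
    abort("`directions` must name every indicator variable")
  }
  directions <- directions[vars]

  std <- standardize_indicators(wide[, c(id_col, vars)])
  X <- as.matrix(std[, vars])
  rownames(X) <- std[[id_col]]

  pca <- prcomp(X, center = TRUE, scale. = FALSE)
  eigenvalues <- pca$sdev^2
  k <- base::length(eigenvalues)
  loadings <- pca$rotation
  scores <- pca$x
  # orientation: direction-weighted loading sum must be non-negative
  for (j in seq_len(k)) {
    if (sum(directions * loadings[, j]) < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  contribution <- eigenvalues / sum(eigenvalues)
  retained <- select_prefix(contribution, threshold)
  weights <- contribution[retained] / sum(contribution[retained])

  U <- vapply(retained, function(j) {
    s <- scores[, j]
    if (max(s) <= min(s)) {
      abort(sprintf("degenerate component score column PC%d", j))
    }
    membership(s, min(s), max(s))
  }, numeric(nrow(X)))
  if (is.null(dim(U))) U <- matrix(U, nrow = nrow(X))
  colnames(U) <- paste0("U", retained)
  d <- drop(U %*% weights)

  per_cultivar <- tibble(cultivar = std[[id_col]]) |>
    dplyr::bind_cols(as_tibble(U)) |>
    mutate(d_value = d, tolerance_class = classify_tolerance(d)) |>
    arrange(dplyr::desc(.data$d_value))

  structure(list(
    scores = per_cultivar,
    loadings = loadings,
    component_scores = scores,
    eigenvalues = eigenvalues,
    contribution = contribution,
    retained = retained,
    weights = weights,
    directions = directions,
    threshold = threshold,
    standardized = std
  ), class = "tolerance_fit")
}

# shortest prefix of components whose cumulative contribution strictly
# exceeds `threshold`; at least one component, all of them if never exceeded
select_prefix <- function(contribution, threshold) {
  first_over <- which(cumsum(contribution) > threshold)[1]
  if (is.na(first_over)) first_over <- base::length(contribution)
  seq_len(first_over)
}

#' Classify D values into tolerance classes
#'
#' Strong when D >= 0.70, moderate when 0.40 <= D < 0.70, weak when
#' D < 0.40 (half-open intervals close the gaps left by the printed
#' 0-0.39 / 0.4-0.69 / 0.7-1 bands).
#'
#' @param d D value(s) in \[0, 1\].
#' @return character vector: "strong", "moderate" or "weak".
#' @export
classify_tolerance <- function(d) {
  if (any(d < -1e-9 | d > 1 + 1e-9)) abort("D outside [0, 1]")
  dplyr::case_when(d >= 0.70 ~ "strong", d >= 0.40 ~ "moderate", TRUE ~ "weak")
}

#' Cluster cultivars on their D values
#'
#' Agglomerative (Ward) clustering with Euclidean distance on D, cut at `k`
#' groups; groups are labelled strong/moderate/weak (for k = 3) by
#' descending mean D. Ties between identical D values fall into the same
#' group deterministically.
#'
#' @param fit a `tolerance_fit`, or a tibble with cultivar and d_value
#'   columns.
#' @param k number of groups (default 3).
#' @return tibble: cultivar, d_value, cluster (integer), cluster_label.
#' @export
cluster_tolerance <- function(fit, k = 3) {
  scores <- if (inherits(fit, "tolerance_fit")) fit$scores else as_tibble(fit)
  k <- check_count(k, "k")
  if (k > nrow(scores)) abort("k exceeds the number of cultivars")
  d <- setNames(scores$d_value, scores$cultivar)
  hc <- hclust(dist(d), method = "ward.D2")
  grp <- cutree(hc, k = k)
  means <- tapply(d, grp, mean)
  ord <- order(means, decreasing = TRUE)  # 1 = highest-D group
  rank_of <- match(grp, ord)
  labels <- if (k == 3) c("strong", "moderate", "weak") else paste0("group", seq_len(k))
  tibble(cultivar = names(d), d_value = unname(d),
         cluster = rank_of, cluster_label = labels[rank_of])
}

#' @describeIn score_tolerance per-cultivar memberships, D value and class.
#' @param x a `tolerance_fit`.
#' @param ... unused.
#' @method tidy tolerance_fit
#' @export
tidy.tolerance_fit <- function(x, ...) x$scores

#' @describeIn score_tolerance one-row summary of the fit.
#' @method glance tolerance_fit
#' @export
glance.tolerance_fit <- function(x, ...) {
  tibble(
    n_cultivars = nrow(x$scores),
    n_variables = nrow(x$loadings),
    n_retained = base::length(x$retained),
    cum_contribution = sum(x$contribution[x$retained]),
    threshold = x$threshold
  )
}

#' @export
print.tolerance_fit <- function(x, ...) {
  cat(sprintf(
    "Comprehensive cold-tolerance fit: %d cultivars, %d indicators\n",
    nrow(x$scores), nrow(x$loadings)
  ))
  cat(sprintf(
    "Retained %d of %d components (cumulative contribution %.1f%% > %.0f%%)\n",
    base::length(x$retained), base::length(x$eigenvalues),
    100 * sum(x$contribution[x$retained]), 100 * x$threshold
  ))
  print(x$scores, ...)
  invisible(x)
}
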