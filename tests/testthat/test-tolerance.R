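test_that("membership function maps range ends to 0 and 1", {
  expect_equal(membership(0, 0, 10), 0)
  expect_equal(membership(10, 0, 10), 1)
  expect_equal(membership(5, 0, 10), 0.5)
  expect_error(membership(1, 3, 3), "degenerate")
  expect_error(membership(11, 0, 10), "outside")
})

test_that("standardization spans [0,1] per column and is idempotent", {
  tbl <- tibble::tibble(cultivar = c("a", "b", "c"), v = c(2, 4, 6))
  std <- standardize_indicators(tbl)
  expect_equal(std$v, c(0, 0.5, 1))
  expect_equal(standardize_indicators(std)$v, std$v)
  expect_error(standardize_indicators(
    tibble::tibble(cultivar = c("a", "b"), v = c(3, 3))), "v")
  expect_error(standardize_indicators(tibble::tibble(cultivar = "a", v = 1)),
               "two cultivars")
})

test_that("component retention takes the shortest prefix above threshold", {
  select_prefix <- coldtol:::select_prefix
  expect_equal(select_prefix(c(0.9, 0.1), 0.85), 1)
  expect_equal(select_prefix(c(0.5, 0.3, 0.15, 0.05), 0.85), 1:3)
  expect_equal(select_prefix(c(1.0), 0.85), 1)
  # weights renormalize the retained contribution rates
  p <- c(0.6, 0.3)
  expect_equal(p / sum(p), c(2 / 3, 1 / 3))
})

test_that("perfectly correlated variables give a rank-1 first component", {
  tbl <- tibble::tibble(cultivar = letters[1:5],
                        v1 = c(1, 2, 3, 4, 5), v2 = c(2, 4, 6, 8, 10))
  fit <- score_tolerance(tbl, directions = c(v1 = 1, v2 = 1))
  expect_equal(fit$contribution[1], 1)
  expect_equal(length(fit$retained), 1)
})

test_that("orientation rule keeps direction-weighted loading sums non-negative", {
  sim <- sim_physiology(8, seed = 77)
  fit <- score_tolerance(sim$indicators)
  for (j in seq_along(fit$eigenvalues)) {
    expect_gte(sum(fit$directions * fit$loadings[, j]), -1e-12)
  }
})

test_that("composite scores match a brute-force eigendecomposition", {
  set.seed(101)
  tbl <- tibble::tibble(cultivar = sprintf("c%02d", 1:14))
  for (v in paste0("v", 1:5)) tbl[[v]] <- runif(14)
  fit <- score_tolerance(tbl,
                         directions = setNames(rep(1, 5), paste0("v", 1:5)))
  X <- as.matrix(standardize_indicators(tbl)[, -1])
  ora <- oracle_pca(X)
  expect_equal(length(fit$eigenvalues), 5)
  expect_equal(sum(fit$contribution), 1, tolerance = 1e-12)
  expect_equal(fit$eigenvalues, ora$values, tolerance = 1e-8)
  for (j in 1:5) {  # scores agree up to the orientation sign
    expect_equal(abs(fit$component_scores[, j]), abs(ora$scores[, j]),
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("three-cultivar fixture reproduces hand-computed D values", {
  # two indicators, both benefit; worked end-to-end with the eigen oracle
  tbl <- tibble::tibble(cultivar = c("lo", "mid", "hi"),
                        v1 = c(10, 20, 40), v2 = c(1, 5, 6))
  fit <- score_tolerance(tbl, directions = c(v1 = 1, v2 = 1), threshold = 0.85)
  std <- cbind(v1 = c(0, 1 / 3, 1), v2 = c(0, 0.8, 1))
  ora <- oracle_pca(std)
  contrib <- ora$values / sum(ora$values)
  retained <- seq_len(which(cumsum(contrib) > 0.85)[1])
  w <- contrib[retained] / sum(contrib[retained])
  U <- vapply(retained, function(j) {
    s <- ora$scores[, j] * sign(sum(ora$vectors[, j])) # orientation, both +1
    (s - min(s)) / (max(s) - min(s))
  }, numeric(3))
  d_oracle <- drop(U %*% w)
  got <- fit$scores[match(tbl$cultivar, fit$scores$cultivar), ]
  expect_equal(got$d_value, d_oracle, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(sum(fit$weights), 1, tolerance = 1e-12)
})

test_that("D is bounded, extreme cultivars hit 0 and 1 with one component", {
  tbl <- tibble::tibble(cultivar = c("a", "b", "c", "d"),
                        v1 = c(1, 2, 3, 4), v2 = c(10, 20, 30, 40))
  fit <- score_tolerance(tbl, directions = c(v1 = 1, v2 = 1))
  expect_equal(length(fit$retained), 1)
  td <- tidy(fit)
  expect_true(all(td$d_value >= 0 & td$d_value <= 1))
  expect_equal(td$d_value[td$cultivar == "d"], 1)
  expect_equal(td$d_value[td$cultivar == "a"], 0)
  # single retained component: D ranking equals the score ranking
  expect_equal(order(fit$component_scores[td$cultivar, 1]),
               order(td$d_value))
})

test_that("D ranking is invariant to affine rescaling of input variables", {
  sim <- sim_physiology(10, seed = 55)
  wide <- aggregate_indicators(sim$indicators)
  fit1 <- score_tolerance(wide)
  scaled <- wide |>
    dplyr::mutate(SOD = 7 * SOD + 100, MDA = 0.3 * MDA - 1)
  fit2 <- score_tolerance(scaled)
  r1 <- tidy(fit1) |> dplyr::arrange(cultivar)
  r2 <- tidy(fit2) |> dplyr::arrange(cultivar)
  expect_equal(rank(r1$d_value), rank(r2$d_value))
  expect_equal(r1$d_value, r2$d_value, tolerance = 1e-8)
})

test_that("noiseless D ranking recovers the latent tolerance ranking", {
  sim <- sim_physiology(12, noise_cv = 0, seed = 99)
  fit <- score_tolerance(sim$indicators)
  joined <- tidy(fit) |> dplyr::left_join(sim$truth, by = "cultivar")
  expect_equal(order(joined$d_value), order(joined$theta))
})

test_that("tolerance classes follow the half-open D thresholds", {
  expect_equal(classify_tolerance(c(0.916, 0.142, 0.40, 0.70, 0.3999, 0.6999)),
               c("strong", "weak", "moderate", "strong", "weak", "moderate"))
  expect_error(classify_tolerance(1.2), "outside")
})

test_that("Ward clustering on D matches brute-force 3-partitions", {
  scores <- tibble::tibble(cultivar = letters[1:5],
                           d_value = c(0.9, 0.88, 0.5, 0.48, 0.1))
  cl <- cluster_tolerance(scores, k = 3)
  # brute-force best contiguous 3-partition by within-group sum of squares
  expect_setequal(cl$cultivar[cl$cluster_label == "strong"], c("a", "b"))
  expect_setequal(cl$cultivar[cl$cluster_label == "moderate"], c("c", "d"))
  expect_setequal(cl$cultivar[cl$cluster_label == "weak"], "e")

  expect_equal(unique(cluster_tolerance(scores, k = 1)$cluster), 1)
  expect_error(cluster_tolerance(scores, k = 9), "exceeds")
  # identical D values: deterministic single-group assignment at k = 2
  flat <- tibble::tibble(cultivar = c("a", "b", "c"), d_value = rep(0.5, 3))
  expect_silent(cluster_tolerance(flat, k = 2))
})

test_that("tidy, glance and autoplot work on a tolerance fit", {
  sim <- sim_physiology(6, seed = 3)
  fit <- score_tolerance(sim$indicators)
  expect_s3_class(tidy(fit), "tbl_df")
  g <- glance(fit)
  expect_equal(g$n_cultivars, 6)
  expect_true(g$cum_contribution > g$threshold)
  expect_s3_class(ggplot2::autoplot(fit), "ggplot")
})
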