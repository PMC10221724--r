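test_that("mean-thickness adjustment removes the covariate by least squares", {
  set.seed(4)
  # residuals are exactly orthogonal to the covariate, with zero mean
  cohort <- generate_cohort(cohort_config(n_subjects_per_group = 15,
                                          n_regions = 10, seed = 8))
  adj <- adjust_for_mean_thickness(cohort[[1]])
  for (j in seq_len(ncol(adj$values))) {
    expect_lt(abs(cor(adj$values[, j], cohort[[1]]$mean_thickness)), 1e-10)
    expect_lt(abs(mean(adj$values[, j])), 1e-12)
  }

  # a region exactly proportional to the covariate leaves zero residuals
  mt <- seq(2, 3, length.out = 4)
  vals <- cbind(2 * mt, 2 * mt + c(0.1, -0.1, 0.1, -0.1))
  tt <- make_table(vals)
  tt$mean_thickness <- mt
  res <- adjust_for_mean_thickness(tt)
  expect_equal(unname(res$values[, 1]), rep(0, 4), tolerance = 1e-12)

  # 5-subject example solved through the normal equations by hand
  x <- 1:5
  e <- c(0.3, -0.2, 0.1, 0.0, -0.2)
  y <- 3 + 0.5 * x + e
  beta <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  alpha <- mean(y) - beta * mean(x)
  expected <- y - alpha - beta * x
  tt <- make_table(cbind(y, y))
  tt$mean_thickness <- x
  res <- adjust_for_mean_thickness(tt)
  expect_equal(unname(res$values[, 1]), expected, tolerance = 1e-12)
})

test_that("adjustment falls back for degenerate inputs with a warning", {
  vals <- matrix(rnorm(20, mean = 3), 5, 4)
  tt <- make_table(vals)
  tt$mean_thickness <- rep(2.5, 5)
  expect_warning(res <- adjust_for_mean_thickness(tt), "constant")
  expect_equal(unname(res$values), unname(scale(vals, scale = FALSE)),
               ignore_attr = TRUE)

  vals2 <- vals
  vals2[, 2] <- 2.7
  tt2 <- make_table(vals2)
  expect_warning(res2 <- adjust_for_mean_thickness(tt2), "r02")
  expect_identical(unname(res2$values[, 2]), rep(0, 5))

  expect_error(adjust_for_mean_thickness(make_table(vals[1:2, ])),
               "3 subjects")
})

test_that("pearson matrix matches the closed-form correlation and its invariants", {
  set.seed(11)
  y1 <- rnorm(6)
  vals <- cbind(y1, y1 + 0, -y1, rnorm(6))
  tt <- make_table(vals)
  cm <- pearson_matrix(tt)
  expect_equal(cm$r[1, 2], 1, tolerance = 1e-12)   # duplicated column
  expect_equal(cm$r[1, 3], -1, tolerance = 1e-12)  # anti-correlated pair
  expect_identical(diag(cm$r), rep(0, 4), ignore_attr = TRUE)
  expect_equal(cm$r, t(cm$r))

  # 3 regions x 4 subjects with integer values vs. the explicit formula
  V <- cbind(c(1, 2, 3, 4), c(2, 1, 4, 3), c(5, 3, 2, 1))
  hand_r <- function(x, y) {
    sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  }
  cm2 <- pearson_matrix(make_table(V))
  for (i in 1:2) {
    for (j in (i + 1):3) {
      expect_equal(cm2$r[i, j], hand_r(V[, i], V[, j]), tolerance = 1e-12)
    }
  }

  # affine rescaling of a region leaves r unchanged
  V2 <- V
  V2[, 2] <- 3.7 * V2[, 2] + 11
  cm3 <- pearson_matrix(make_table(V2))
  expect_equal(cm3$r, cm2$r, tolerance = 1e-12, ignore_attr = TRUE)

  # zero-variance region zeroed with warning
  V3 <- cbind(V, 7)
  expect_warning(cm4 <- pearson_matrix(make_table(V3)), "zero-variance")
  expect_identical(unname(cm4$r[4, ]), rep(0, 4))
})

test_that("binarization realizes the exact edge count with signed ranking", {
  set.seed(21)
  cm5 <- random_covariance(5)
  # the complete graph at d = 1 necessarily admits negative correlations
  expect_warning(k5 <- binarize_at_density(cm5, 1), "admitted")
  expect_equal(sum(k5$a) / 2, 10)

  cm68 <- random_covariance(68)
  a <- binarize_at_density(cm68, 0.17)
  expect_equal(sum(a$a) / 2, 387)  # round(0.17 * 2278)
  expect_identical(diag(a$a), rep(0L, 68), ignore_attr = TRUE)
  expect_identical(a$a, t(a$a))

  # 5 nodes, 10 distinct hand-ranked values, d = 0.3 -> exactly the top 3
  r <- matrix(0, 5, 5)
  vals <- c(0.9, 0.8, 0.7, 0.6, 0.5, 0.4, 0.3, 0.2, 0.1, 0.05)
  pairs <- combn(5, 2)
  for (k in 1:10) r[pairs[1, k], pairs[2, k]] <- r[pairs[2, k], pairs[1, k]] <- vals[k]
  diag(r) <- 0
  dimnames(r) <- list(letters[1:5], letters[1:5])
  a3 <- binarize_at_density(covariance_matrix(r), 0.3)
  expect_equal(sum(a3$a) / 2, 3)
  expect_equal(a3$a["a", "b"], 1, ignore_attr = TRUE)  # 0.9
  expect_equal(a3$a["a", "c"], 1, ignore_attr = TRUE)  # 0.8
  expect_equal(a3$a["a", "d"], 1, ignore_attr = TRUE)  # 0.7
  expect_equal(a3$a["a", "e"], 0, ignore_attr = TRUE)  # 0.6 ranked fourth

  # ranking is signed: admitting negatives is warned about
  rneg <- -abs(r); diag(rneg) <- 0
  expect_warning(binarize_at_density(covariance_matrix(rneg), 0.5),
                 "admitted")
})

test_that("edge sets are nested along increasing densities", {
  set.seed(33)
  cm <- random_covariance(20)
  ds <- seq(0.1, 0.9, by = 0.1)
  adjs <- binarize_grid(cm, ds)
  for (k in 2:length(ds)) {
    expect_true(all(adjs[[k]]$a >= adjs[[k - 1]]$a))
    expect_equal(sum(adjs[[k]]$a) / 2,
                 round(ds[k] * 190))
  }
  # binarize_grid agrees with one-shot binarization
  one <- binarize_at_density(cm, 0.3)
  expect_identical(adjs[["0.30"]]$a, one$a)
})

test_that("minimum connected density matches a brute-force scan", {
  brute_dmin <- function(cm, resolution = 0.01) {
    for (k in seq_len(round(1 / resolution))) {
      d <- k * resolution
      a <- suppressWarnings(binarize_at_density(cm, d))
      g <- igraph::graph_from_adjacency_matrix(a$a, mode = "undirected")
      if (igraph::is_connected(g)) return(d)
    }
    1
  }

  # ranking whose top N-1 pairs form a spanning tree over N = 10
  n <- 10
  r <- matrix(0, n, n)
  pairs <- combn(n, 2)
  # top-ranked pairs: the path over consecutive nodes (a spanning tree)
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    r[i, j] <- r[j, i] <- if (j == i + 1) 1 - 0.001 * i else 0.5 - 0.001 * k
  }
  diag(r) <- 0
  dimnames(r) <- list(sprintf("n%02d", 1:n), sprintf("n%02d", 1:n))
  cm <- covariance_matrix(r)
  expect_equal(minimum_connected_density(cm), brute_dmin(cm))

  # seeded random matrices agree with the brute-force oracle
  set.seed(55)
  for (rep in 1:5) {
    cm <- random_covariance(12)
    expect_equal(minimum_connected_density(cm), brute_dmin(cm))
    # refining the grid can only lower the estimate
    expect_lte(minimum_connected_density(cm, 0.001),
               minimum_connected_density(cm, 0.01))
  }
})

test_that("networks at or above the minimum density are connected", {
  set.seed(77)
  for (rep in 1:5) {
    cm <- random_covariance(15)
    dmin <- minimum_connected_density(cm)
    for (d in unique(pmin(1, dmin + c(0, 0.05, 0.2)))) {
      a <- suppressWarnings(binarize_at_density(cm, d))
      g <- igraph::graph_from_adjacency_matrix(a$a, mode = "undirected")
      expect_true(igraph::is_connected(g))
    }
  }
})

test_that("density grids anchor at the pairwise lower bound", {
  g1 <- build_density_grid(0.17, 0.11)
  expect_equal(g1$densities, seq(0.17, 0.47, by = 0.05))
  expect_equal(max(g1$densities), 0.47)

  g2 <- build_density_grid(0.09, 0.11)
  expect_equal(g2$densities, seq(0.11, 0.46, by = 0.05))
  expect_equal(max(g2$densities), 0.46)

  g3 <- build_density_grid(0.40, 0.40)
  expect_equal(g3$densities, c(0.40, 0.45, 0.50))  # upper hit exactly

  expect_error(build_density_grid(0.6, 0.2), "exceeds upper")
  expect_error(build_density_grid(0, 0.2), "positive")
})
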