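# two small groups with disjoint subject ids, shared regions
two_groups <- function(seed = 1, n = 10, p = 12, effects = c(A = 1, B = 1)) {
  generate_cohort(cohort_config(n_subjects_per_group = n, n_regions = p,
                                group_effects = effects, seed = seed))
}

test_that("the functional statistic is the normalized trapezoidal area", {
  d <- c(0.1, 0.15, 0.2)
  expect_equal(fda_statistic(c(1, 2, 3), c(1, 2, 3), d), 0)
  expect_equal(fda_statistic(c(1, 2, 3), c(1, 2, 3) - 0.25, d), 0.25)
  # hand trapezoid: differences (0.2, 0.4, 0.6) -> area 0.04, span 0.1
  expect_equal(fda_statistic(c(0.2, 0.4, 0.6), c(0, 0, 0), d), 0.4)
  # single-density grid degenerates to the plain difference
  expect_equal(fda_statistic(0.7, 0.2, 0.3), 0.5)
  # antisymmetry in the group order
  expect_equal(fda_statistic(c(0.2, 0.4, 0.6), c(0.1, 0.1, 0.1), d),
               -fda_statistic(c(0.1, 0.1, 0.1), c(0.2, 0.4, 0.6), d))

  expect_error(fda_statistic(c(1, 2), c(1, 2, 3), d), "identical length")
  expect_error(fda_statistic(c(1, 2, 3), c(1, 2, 3), c(0.2, 0.1, 0.3)),
               "increasing")
})

test_that("input validation rejects malformed comparisons", {
  gr <- two_groups()
  expect_error(scn_permutation_test(gr$A, gr$B, c(0.2, 0.3), n_perm = 0),
               "n_perm")
  dup <- gr$B
  dup$subject_ids <- gr$A$subject_ids
  rownames(dup$values) <- dup$subject_ids
  expect_error(scn_permutation_test(gr$A, dup, c(0.2, 0.3)), "unique")
  small <- gr$B
  small$region_labels <- small$region_labels[1:6]
  small$values <- small$values[, 1:6]
  expect_error(scn_permutation_test(gr$A, small, c(0.2, 0.3)),
               "region labels")
})

test_that("the unpermuted pipeline reproduces the observed curves exactly", {
  gr <- two_groups(seed = 2)
  d <- c(0.2, 0.3, 0.4)
  tst <- scn_permutation_test(gr$A, gr$B, d, global_metrics = "cc_glob",
                              nodal_metrics = "degree", n_perm = 5, seed = 3)
  mc <- metric_curves(gr$A, d, global_metrics = "cc_glob",
                      nodal_metrics = "degree")
  expect_equal(tst$curves$a$global, mc$global)
  expect_equal(tst$curves$a$nodal$degree, mc$nodal$degree)
})

test_that("identical groups give a zero statistic and p of one", {
  gr <- two_groups(seed = 4)
  copy <- gr$A
  copy$group_label <- "B"
  copy$subject_ids <- sub("^A", "B", copy$subject_ids)
  rownames(copy$values) <- copy$subject_ids
  tst <- scn_permutation_test(gr$A, copy, c(0.2, 0.3, 0.4),
                              global_metrics = c("cc_glob", "l", "e_glob"),
                              nodal_metrics = "cc_node",
                              n_perm = 49, seed = 5)
  expect_equal(unname(tst$observed_global), rep(0, 3))
  expect_equal(unname(tst$p_fda_global), rep(1, 3))
  expect_equal(unname(tst$p_fda_nodal$cc_node),
               rep(1, length(tst$p_fda_nodal$cc_node)))
})

test_that("swapping the contrast order negates the statistic, not the p-value", {
  gr <- two_groups(seed = 6, effects = c(A = 1, B = 0.6))
  d <- c(0.2, 0.3, 0.4)
  ab <- scn_permutation_test(gr$A, gr$B, d, global_metrics = "cc_glob",
                             nodal_metrics = "degree", n_perm = 49, seed = 7)
  ba <- scn_permutation_test(gr$B, gr$A, d, global_metrics = "cc_glob",
                             nodal_metrics = "degree", n_perm = 49, seed = 7)
  expect_equal(ab$observed_global[["cc_glob"]],
               -ba$observed_global[["cc_glob"]])
  expect_identical(ab$p_fda_global[["cc_glob"]],
                   ba$p_fda_global[["cc_glob"]])
  expect_equal(unname(ab$observed_nodal$degree),
               -unname(ba$observed_nodal$degree))
  expect_identical(unname(ab$p_fda_nodal$degree),
                   unname(ba$p_fda_nodal$degree))
})

test_that("p-values stay within (0, 1] and runs are seed-reproducible", {
  gr <- two_groups(seed = 8)
  d <- c(0.25, 0.35)
  t1 <- scn_permutation_test(gr$A, gr$B, d, global_metrics = "cc_glob",
                             nodal_metrics = "e_loc", n_perm = 29, seed = 11)
  t2 <- scn_permutation_test(gr$A, gr$B, d, global_metrics = "cc_glob",
                             nodal_metrics = "e_loc", n_perm = 29, seed = 11)
  expect_identical(t1$null_global, t2$null_global)
  expect_identical(t1$p_fda_nodal, t2$p_fda_nodal)
  expect_true(all(t1$p_fda_global > 0 & t1$p_fda_global <= 1))
  expect_true(all(t1$p_fda_nodal$e_loc > 0 & t1$p_fda_nodal$e_loc <= 1))
})

test_that("the single-metric wrapper mirrors the engine", {
  gr <- two_groups(seed = 9)
  d <- c(0.25, 0.35)
  full <- scn_permutation_test(gr$A, gr$B, d, global_metrics = "cc_glob",
                               nodal_metrics = character(0), n_perm = 19,
                               seed = 13)
  one <- permute_and_compare(gr$A, gr$B, "cc_glob", d, n_perm = 19, seed = 13)
  expect_equal(one$observed_stat, unname(full$observed_global["cc_glob"]))
  expect_equal(one$p_fda, unname(full$p_fda_global["cc_glob"]))
  expect_length(one$null_stats, 19)
  expect_error(permute_and_compare(gr$A, gr$B, "betweenness", d), "unknown")
})

test_that("a strong segregation perturbation is detected with the right sign", {
  # halving the within-module correlation of group B must lower its
  # clustering curve; the observed statistic (A - B) is positive and
  # significant at this seed
  gr <- two_groups(seed = 10, n = 21, p = 68, effects = c(A = 1, B = 0.5))
  dmin <- vapply(gr, function(t)
    minimum_connected_density(pearson_matrix(adjust_for_mean_thickness(t))),
    numeric(1))
  grid <- build_density_grid(dmin[[1]], dmin[[2]])
  tst <- scn_permutation_test(gr$A, gr$B, grid, global_metrics = "cc_glob",
                              nodal_metrics = character(0), n_perm = 99,
                              seed = 15)
  expect_gt(tst$observed_global[["cc_glob"]], 0)
  expect_lt(tst$p_fda_global[["cc_glob"]], 0.05)
})

test_that("three-group comparison flags only contrasts with the perturbed group", {
  cohort <- generate_cohort(cohort_config(
    n_subjects_per_group = 21, n_regions = 68,
    group_effects = c(HC = 1, SZND = 1, SZD = 0.5), seed = 12))
  fit <- scn_compare(cohort, global_metrics = "cc_glob",
                     nodal_metrics = character(0), n_perm = 99, seed = 17)
  expect_s3_class(fit, "scn_comparison")
  # grids anchor at the pairwise maximum of the groups' minimum densities
  for (key in names(fit$grids)) {
    parts <- strsplit(key, " vs ")[[1]]
    expect_equal(fit$grids[[key]]$lower,
                 max(fit$d_min[[parts[1]]], fit$d_min[[parts[2]]]))
  }
  gl <- fit$global_results
  p_null <- gl$p_fda[gl$contrast == "HC vs SZND"]
  p_szd <- gl$p_fda[gl$contrast %in% c("HC vs SZD", "SZND vs SZD")]
  expect_gt(p_null, 0.05)
  expect_true(all(p_szd < 0.05))
})

test_that("three identical tables yield no significant contrast", {
  one <- generate_cohort(cohort_config(n_subjects_per_group = 12,
                                       n_regions = 16,
                                       group_effects = c(G = 1), seed = 14))$G
  tables <- lapply(c("X", "Y", "Z"), function(g) {
    t <- one
    t$group_label <- g
    t$subject_ids <- sub("^G", g, t$subject_ids)
    rownames(t$values) <- t$subject_ids
    t
  })
  fit <- scn_compare(tables, global_metrics = "cc_glob",
                     nodal_metrics = "degree", n_perm = 29, seed = 19)
  expect_true(all(fit$global_results$p_fda == 1))
  expect_true(all(fit$global_results$observed_stat == 0))
  s <- summary(fit)
  expect_identical(nrow(s$significant_nodes), 0L)
})

test_that("node-level FDR correction is monotone and optional", {
  gr <- two_groups(seed = 16)
  fit <- scn_compare(gr, global_metrics = character(0),
                     nodal_metrics = "degree", n_perm = 19, seed = 21,
                     node_fdr = TRUE)
  nr <- fit$nodal_results
  expect_true("p_fda_fdr" %in% names(nr))
  expect_true(all(nr$p_fda_fdr >= nr$p_fda - 1e-12))
})
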