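# Permutation group comparison with a functional summary across densities.

# Trapezoid weights over a density grid; the weighted sum of a difference
# curve divided by the grid span is the mean functional difference.
trapezoid_weights <- function(d) {
  nd <- length(d)
  if (nd == 1) return(1)
  w <- numeric(nd)
  w[1] <- (d[2] - d[1]) / 2
  w[nd] <- (d[nd] - d[nd - 1]) / 2
  if (nd > 2) w[2:(nd - 1)] <- (d[3:nd] - d[1:(nd - 2)]) / 2
  w
}

#' Functional difference statistic across densities
#'
#' Summarizes a between-group difference curve over the whole density range
#' as the trapezoidal integral of `curve_a - curve_b` divided by the grid
#' span, i.e. the mean functional difference (sign preserved). Integrating
#' across densities is what makes the subsequent permutation p-value a
#' density-range-wide test rather than a per-density one.
#'
#' @param curve_a,curve_b Numeric vectors of metric values on the same
#'   density grid (or `metric_curves` global rows).
#' @param densities Strictly increasing density grid shared by both curves.
#' @return A single number; zero for identical curves, `c` for a constant
#'   difference `c`.
#' @export
#' @examples
#' fda_statistic(c(0.5, 0.7, 0.9), c(0.3, 0.3, 0.3), c(0.1, 0.15, 0.2))
fda_statistic <- function(curve_a, curve_b, densities) {
  stopifnot(is.numeric(curve_a), is.numeric(curve_b), is.numeric(densities))
  if (length(curve_a) != length(densities) ||
      length(curve_b) != length(densities))
    stop("curves and density grid must have identical length")
  if (length(densities) > 1 && any(diff(densities) <= 0))
    stop("densities must be strictly increasing")
  if (!all(is.finite(curve_a)) || !all(is.finite(curve_b)))
    stop("curve values must be finite")
  diff_curve <- curve_a - curve_b
  if (length(densities) == 1) return(diff_curve)
  span <- densities[length(densities)] - densities[1]
  sum(trapezoid_weights(densities) * diff_curve) / span
}

# Apply the FDA statistic row-wise to matrices of curves (rows = metrics or
# nodes, columns = densities).
fda_rows <- function(mat_a, mat_b, w, span) {
  as.vector(((mat_a - mat_b) %*% w) / span)
}

# Plus-one two-tailed percentile p-value.
perm_pvalue <- function(observed, nulls) {
  (1 + sum(abs(nulls) >= abs(observed))) / (length(nulls) + 1)
}

#' Permutation comparison of two groups across a density grid
#'
#' The full two-group pipeline under subject-relabeling permutations. For
#' each of `n_perm` permutations, subjects (entire regional vectors, with
#' their mean thickness) are reassigned without replacement to two groups of
#' the original sizes; the whole per-group pipeline — mean-thickness
#' adjustment, Pearson matrix, binarization at every grid density, metric
#' curves — is recomputed for both permuted groups, and the
#' [fda_statistic()] of each requested metric (and node, for nodal metrics)
#' is collected into a null distribution. Two-tailed p-values use the
#' plus-one percentile estimator `(1 + #{|null| >= |obs|}) / (n_perm + 1)`.
#'
#' Subjects are pooled in a canonical (sorted-id) order before permuting, so
#' swapping the argument order negates every observed statistic but leaves
#' the null distributions — and hence the p-values — identical for
#' equal-sized groups.
#'
#' @param table_a,table_b Raw [thickness_table()]s with identical region
#'   labels and disjoint subject ids.
#' @param densities Shared density grid (numeric or [build_density_grid()]).
#' @param global_metrics,nodal_metrics Metric names (see [metric_curves()]).
#' @param n_perm Number of permutations (default 1000).
#' @param n_null,swap_factor Sigma null-model settings, only used when
#'   `"sigma"` is requested.
#' @param seed Integer seed; results are fully reproducible.
#' @return An object of class `scn_permutation_test`: observed curves for
#'   both groups, per-metric observed statistics, null statistics and
#'   `p_fda`, and per-node results for nodal metrics.
#' @export
scn_permutation_test <- function(table_a, table_b, densities,
                                 global_metrics = c("cc_glob", "l", "e_glob"),
                                 nodal_metrics = c("degree", "cc_node", "e_loc"),
                                 n_perm = 1000, n_null = 20, swap_factor = 10,
                                 seed = 1) {
  stopifnot(inherits(table_a, "thickness_table"),
            inherits(table_b, "thickness_table"))
  check_same_regions(list(table_a, table_b))
  if (inherits(densities, "density_grid")) densities <- densities$densities
  if (length(densities) < 1 || any(densities <= 0) || any(densities > 1) ||
      (length(densities) > 1 && any(diff(densities) <= 0)))
    stop("densities must be a strictly increasing grid in (0, 1]")
  if (!is_scalar_number(n_perm) || n_perm < 1)
    stop("n_perm must be a positive integer")
  n_perm <- as.integer(n_perm)
  ids <- c(table_a$subject_ids, table_b$subject_ids)
  if (anyDuplicated(ids))
    stop("subject ids must be unique across the two groups")
  global_metrics <- if (length(global_metrics))
    match.arg(global_metrics, GLOBAL_METRICS, several.ok = TRUE) else character(0)
  nodal_metrics <- if (length(nodal_metrics))
    match.arg(nodal_metrics, NODAL_METRICS, several.ok = TRUE) else character(0)

  n_a <- nrow(table_a$values)
  n_b <- nrow(table_b$values)
  # Canonical pooled order: sorted subject ids, independent of argument order.
  pooled_v <- rbind(table_a$values, table_b$values)
  pooled_mt <- c(table_a$mean_thickness, table_b$mean_thickness)
  ord <- order(ids, method = "radix")
  pooled_v <- pooled_v[ord, , drop = FALSE]
  pooled_mt <- pooled_mt[ord]
  n_tot <- n_a + n_b

  w <- trapezoid_weights(densities)
  span <- if (length(densities) > 1)
    densities[length(densities)] - densities[1] else 1

  curves <- function(v, mt, sig_seed) {
    group_curves_matrix(v, mt, densities, global_metrics, nodal_metrics,
                        n_null = n_null, seed = sig_seed,
                        swap_factor = swap_factor)
  }
  obs_a <- curves(table_a$values, table_a$mean_thickness,
                  sub_seed(seed, "sigma_obs_a"))
  obs_b <- curves(table_b$values, table_b$mean_thickness,
                  sub_seed(seed, "sigma_obs_b"))

  obs_global <- if (length(global_metrics))
    structure(fda_rows(obs_a$global, obs_b$global, w, span),
              names = global_metrics) else numeric(0)
  obs_nodal <- lapply(nodal_metrics, function(m)
    structure(fda_rows(obs_a$nodal[[m]], obs_b$nodal[[m]], w, span),
              names = table_a$region_labels))
  names(obs_nodal) <- nodal_metrics

  null_global <- matrix(NA_real_, n_perm, length(global_metrics),
                        dimnames = list(NULL, global_metrics))
  null_nodal <- lapply(nodal_metrics, function(m)
    matrix(NA_real_, n_perm, length(table_a$region_labels),
           dimnames = list(NULL, table_a$region_labels)))
  names(null_nodal) <- nodal_metrics

  with_preserved_seed(sub_seed(seed, "permutation"), {
    for (k in seq_len(n_perm)) {
      idx <- sample.int(n_tot, n_a)
      pa <- curves(pooled_v[idx, , drop = FALSE], pooled_mt[idx],
                   sub_seed(seed, sprintf("sigma_perm_a%05d", k)))
      pb <- curves(pooled_v[-idx, , drop = FALSE], pooled_mt[-idx],
                   sub_seed(seed, sprintf("sigma_perm_b%05d", k)))
      if (length(global_metrics))
        null_global[k, ] <- fda_rows(pa$global, pb$global, w, span)
      for (m in nodal_metrics)
        null_nodal[[m]][k, ] <- fda_rows(pa$nodal[[m]], pb$nodal[[m]], w, span)
    }
  })

  p_global <- vapply(seq_along(global_metrics), function(i)
    perm_pvalue(obs_global[i], null_global[, i]), numeric(1))
  names(p_global) <- global_metrics
  p_nodal <- lapply(nodal_metrics, function(m)
    vapply(seq_along(obs_nodal[[m]]), function(i)
      perm_pvalue(obs_nodal[[m]][i], null_nodal[[m]][, i]), numeric(1)))
  names(p_nodal) <- nodal_metrics
  for (m in nodal_metrics) names(p_nodal[[m]]) <- table_a$region_labels

  structure(
    list(contrast = c(table_a$group_label, table_b$group_label),
         densities = densities,
         curves = list(a = obs_a, b = obs_b),
         observed_global = obs_global, null_global = null_global,
         p_fda_global = p_global,
         observed_nodal = obs_nodal, null_nodal = null_nodal,
         p_fda_nodal = p_nodal,
         n_perm = n_perm, seed = seed),
    class = "scn_permutation_test")
}

#' @export
print.scn_permutation_test <- function(x, ...) {
  cat(sprintf("Permutation comparison %s vs %s (%d permutations, %d densities)\n",
              x$contrast[1], x$contrast[2], x$n_perm, length(x$densities)))
  if (length(x$observed_global)) {
    cat("  global metrics (FDA statistic, p_FDA):\n")
    for (m in names(x$observed_global))
      cat(sprintf("    %-8s %+0.4f  p = %.3f\n", m, x$observed_global[m],
                  x$p_fda_global[m]))
  }
  for (m in names(x$p_fda_nodal)) {
    sig <- sum(x$p_fda_nodal[[m]] < 0.05)
    cat(sprintf("  nodal %-8s %d/%d nodes with p_FDA < 0.05\n", m, sig,
                length(x$p_fda_nodal[[m]])))
  }
  invisible(x)
}

#' Single-metric permutation comparison
#'
#' Convenience wrapper around [scn_permutation_test()] for one metric.
#'
#' @param table_a,table_b Raw [thickness_table()]s.
#' @param metric One of `"cc_glob"`, `"l"`, `"e_glob"`, `"sigma"` (global) or
#'   `"degree"`, `"cc_node"`, `"e_loc"` (nodal).
#' @param densities Shared density grid.
#' @param n_perm,n_null,seed See [scn_permutation_test()].
#' @return For a global metric, a list with `contrast`, `metric`,
#'   `observed_stat`, `null_stats`, `n_perm`, `p_fda`, `seed` (class
#'   `permutation_comparison`); for a nodal metric, the same with per-node
#'   vectors.
#' @export
permute_and_compare <- function(table_a, table_b, metric, densities,
                                n_perm = 1000, n_null = 20, seed = 1) {
  stopifnot(length(metric) == 1)
  is_global <- metric %in% GLOBAL_METRICS
  if (!is_global && !metric %in% NODAL_METRICS)
    stop("unknown metric '", metric, "'")
  res <- scn_permutation_test(
    table_a, table_b, densities,
    global_metrics = if (is_global) metric else character(0),
    nodal_metrics = if (is_global) character(0) else metric,
    n_perm = n_perm, n_null = n_null, seed = seed)
  out <- if (is_global) {
    list(contrast = res$contrast, metric = metric,
         observed_stat = unname(res$observed_global[metric]),
         null_stats = as.vector(res$null_global[, metric]),
         n_perm = res$n_perm,
         p_fda = unname(res$p_fda_global[metric]), seed = seed)
  } else {
    list(contrast = res$contrast, metric = metric,
         observed_stat = res$observed_nodal[[metric]],
         null_stats = res$null_nodal[[metric]],
         n_perm = res$n_perm,
         p_fda = res$p_fda_nodal[[metric]], seed = seed)
  }
  structure(out, class = "permutation_comparison")
}

#' @export
print.permutation_comparison <- function(x, ...) {
  cat(sprintf("Permutation comparison %s vs %s, metric %s (%d permutations)\n",
              x$contrast[1], x$contrast[2], x$metric, x$n_perm))
  if (length(x$p_fda) == 1) {
    cat(sprintf("  observed = %+0.4f, p_FDA = %.3f\n", x$observed_stat,
                x$p_fda))
  } else {
    cat(sprintf("  %d nodes; %d with p_FDA < 0.05\n", length(x$p_fda),
                sum(x$p_fda < 0.05)))
  }
  invisible(x)
}
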