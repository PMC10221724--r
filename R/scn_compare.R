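#' Structural covariance network comparison of multiple groups
#'
#' The end-to-end analysis: for every group, the minimum connected density of
#' its covariance network is estimated; for every pairwise contrast, a shared
#' density grid is anchored at the larger of the two minimum densities and a
#' full permutation comparison ([scn_permutation_test()]) is run for the
#' requested global and nodal metrics. Nodal p-values are corrected across
#' the density range by construction (the functional statistic integrates
#' over it) but not across nodes; set `node_fdr = TRUE` for an additional
#' Benjamini-Hochberg correction across nodes.
#'
#' @param tables Named list of 2 or more raw [thickness_table()]s sharing
#'   region labels (typically 3 groups).
#' @param step,upper Density-grid step and upper bound (defaults 0.05, 0.5).
#' @param dmin_resolution Resolution of the minimum-density search (default
#'   0.01).
#' @param global_metrics,nodal_metrics Metrics to test (see
#'   [metric_curves()]).
#' @param n_perm Permutations per contrast (default 1000).
#' @param n_null,swap_factor Sigma null settings (see [small_world_sigma()]).
#' @param seed Root seed; each contrast's permutation stream is derived from
#'   it.
#' @param node_fdr Add a `p_fda_fdr` column (BH across nodes, per contrast
#'   and metric).
#' @return An object of class `scn_comparison` with components `d_min`
#'   (per group), `grids` and `tests` (per contrast), tidy result tables
#'   `global_results` and `nodal_results`, and the call settings.
#' @export
#' @examples
#' cfg <- cohort_config(n_subjects_per_group = 12, n_regions = 16,
#'                      group_effects = c(A = 1, B = 1), seed = 7)
#' fit <- scn_compare(generate_cohort(cfg), n_perm = 49,
#'                    global_metrics = "cc_glob", nodal_metrics = "degree")
#' print(fit)
scn_compare <- function(tables, step = 0.05, upper = 0.5,
                        dmin_resolution = 0.01,
                        global_metrics = c("cc_glob", "l", "e_glob"),
                        nodal_metrics = c("degree", "cc_node", "e_loc"),
                        n_perm = 1000, n_null = 20, swap_factor = 10,
                        seed = 1, node_fdr = FALSE) {
  stopifnot(is.list(tables), length(tables) >= 2)
  lapply(tables, function(t) stopifnot(inherits(t, "thickness_table")))
  check_same_regions(tables)
  groups <- vapply(tables, function(t) t$group_label, character(1))
  if (anyDuplicated(groups)) stop("group labels must be unique")
  names(tables) <- groups

  d_min <- vapply(tables, function(t)
    minimum_connected_density(pearson_matrix(adjust_for_mean_thickness(t)),
                              resolution = dmin_resolution),
    numeric(1))

  contrasts <- utils::combn(groups, 2, simplify = FALSE)
  grids <- list()
  tests <- list()
  for (ct in contrasts) {
    key <- paste(ct, collapse = " vs ")
    grids[[key]] <- build_density_grid(d_min[[ct[1]]], d_min[[ct[2]]],
                                       step = step, upper = upper)
    tests[[key]] <- scn_permutation_test(
      tables[[ct[1]]], tables[[ct[2]]], grids[[key]],
      global_metrics = global_metrics, nodal_metrics = nodal_metrics,
      n_perm = n_perm, n_null = n_null, swap_factor = swap_factor,
      seed = sub_seed(seed, paste0("perm:", key)))
  }

  measure_class <- c(degree = "Centrality", cc_node = "Segregation",
                     e_loc = "Integration", cc_glob = "Segregation",
                     l = "Integration", e_glob = "Integration",
                     sigma = "Small-world")

  global_rows <- list()
  nodal_rows <- list()
  for (key in names(tests)) {
    tst <- tests[[key]]
    for (m in names(tst$observed_global)) {
      global_rows[[length(global_rows) + 1L]] <- data.frame(
        contrast = key, measure_class = unname(measure_class[m]), metric = m,
        avg_a = mean(tst$curves$a$global[m, ]),
        avg_b = mean(tst$curves$b$global[m, ]),
        observed_stat = unname(tst$observed_global[m]),
        p_fda = unname(tst$p_fda_global[m]), row.names = NULL)
    }
    for (m in names(tst$p_fda_nodal)) {
      nodal_rows[[length(nodal_rows) + 1L]] <- data.frame(
        contrast = key, measure_class = unname(measure_class[m]), metric = m,
        node = tst$curves$a$nodal[[m]] |> rownames(),
        avg_a = rowMeans(tst$curves$a$nodal[[m]]),
        avg_b = rowMeans(tst$curves$b$nodal[[m]]),
        observed_stat = unname(tst$observed_nodal[[m]]),
        p_fda = unname(tst$p_fda_nodal[[m]]), row.names = NULL)
    }
  }
  global_results <- if (length(global_rows)) do.call(rbind, global_rows) else
    data.frame()
  nodal_results <- if (length(nodal_rows)) do.call(rbind, nodal_rows) else
    data.frame()
  if (node_fdr && nrow(nodal_results)) {
    nodal_results$p_fda_fdr <- stats::ave(
      nodal_results$p_fda,
      paste(nodal_results$contrast, nodal_results$metric),
      FUN = function(p) stats::p.adjust(p, method = "BH"))
  }

  structure(
    list(groups = groups, d_min = d_min, grids = grids, tests = tests,
         global_results = global_results, nodal_results = nodal_results,
         settings = list(step = step, upper = upper,
                         dmin_resolution = dmin_resolution,
                         global_metrics = global_metrics,
                         nodal_metrics = nodal_metrics, n_perm = n_perm,
                         n_null = n_null, swap_factor = swap_factor,
                         seed = seed, node_fdr = node_fdr)),
    class = "scn_comparison")
}

#' @export
print.scn_comparison <- function(x, ...) {
  cat("Structural covariance network comparison\n")
  cat(sprintf("  groups: %s\n", paste(
    sprintf("%s (D_min %.2f)", x$groups, x$d_min), collapse = ", ")))
  for (key in names(x$grids)) {
    g <- x$grids[[key]]
    cat(sprintf("  %-18s grid %.2f-%.2f", key, min(g$densities),
                max(g$densities)))
    gl <- x$global_results[x$global_results$contrast == key, , drop = FALSE]
    if (nrow(gl))
      cat(sprintf("; global p_FDA: %s", paste(
        sprintf("%s %.3f", gl$metric, gl$p_fda), collapse = ", ")))
    cat("\n")
  }
  if (nrow(x$nodal_results)) {
    sig <- x$nodal_results[x$nodal_results$p_fda < 0.05, , drop = FALSE]
    cat(sprintf("  nodal tests: %d, of which %d with p_FDA < 0.05\n",
                nrow(x$nodal_results), nrow(sig)))
  }
  cat(sprintf("  %d permutations per contrast, seed %d\n",
              x$settings$n_perm, x$settings$seed))
  invisible(x)
}

#' @export
summary.scn_comparison <- function(object, alpha = 0.05, ...) {
  out <- list(
    d_min = object$d_min,
    global = object$global_results,
    significant_nodes = if (nrow(object$nodal_results))
      object$nodal_results[object$nodal_results$p_fda < alpha, , drop = FALSE]
      else object$nodal_results,
    alpha = alpha)
  class(out) <- "summary.scn_comparison"
  out
}

#' @export
print.summary.scn_comparison <- function(x, ...) {
  cat("Global metrics (group averages across densities, p_FDA):\n")
  print(x$global, row.names = FALSE, digits = 3)
  cat(sprintf("\nNodal results with p_FDA < %.2f:\n", x$alpha))
  if (nrow(x$significant_nodes)) {
    print(x$significant_nodes, row.names = FALSE, digits = 3)
  } else {
    cat("  none\n")
  }
  invisible(x)
}

#' Plot metric curves across densities
#'
#' Draws one global metric's curve per group for a chosen contrast, the raw
#' material of the functional comparison.
#'
#' @param x An [scn_compare()] result.
#' @param metric Global metric to plot (default: first available).
#' @param contrast Contrast name (default: first).
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.scn_comparison <- function(x, metric = NULL, contrast = NULL, ...) {
  if (is.null(contrast)) contrast <- names(x$tests)[1]
  tst <- x$tests[[contrast]]
  if (is.null(tst)) stop("unknown contrast '", contrast, "'")
  if (is.null(metric)) metric <- rownames(tst$curves$a$global)[1]
  ya <- tst$curves$a$global[metric, ]
  yb <- tst$curves$b$global[metric, ]
  graphics::matplot(tst$densities, cbind(ya, yb), type = "b", pch = c(1, 2),
                    lty = 1, col = c("black", "firebrick"),
                    xlab = "density", ylab = metric,
                    main = sprintf("%s (p_FDA = %.3f)", contrast,
                                   tst$p_fda_global[metric]), ...)
  graphics::legend("topleft", legend = tst$contrast, pch = c(1, 2),
                   col = c("black", "firebrick"), bty = "n")
  invisible(x)
}
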