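#' Adjust regional thickness for overall mean thickness
#'
#' Residualizes every region on the per-subject overall mean thickness by
#' ordinary least squares (intercept + slope), within one group. The returned
#' residuals are exactly uncorrelated with the covariate and have zero mean,
#' so subsequent covariance networks reflect regional co-variation beyond the
#' shared global thickness. If the covariate is constant across subjects the
#' regression is undefined and the function falls back to mean-centering (with
#' a warning); a constant region column yields an all-zero residual column
#' (with a warning naming the region).
#'
#' @param table A raw [thickness_table()] with at least 3 subjects.
#' @return A [thickness_table()] of residuals (attribute `adjusted = TRUE`);
#'   `mean_thickness` is carried over unchanged.
#' @export
adjust_for_mean_thickness <- function(table) {
  stopifnot(inherits(table, "thickness_table"))
  V <- table$values
  if (nrow(V) < 3) stop("adjustment requires at least 3 subjects")
  x <- table$mean_thickness
  const_cols <- apply(V, 2, function(col) diff(range(col)) == 0)
  if (stats::sd(x) == 0) {
    warning("mean thickness is constant across subjects; ",
            "falling back to mean-centering")
    res <- scale(V, center = TRUE, scale = FALSE)
    attr(res, "scaled:center") <- NULL
  } else {
    res <- qr.resid(qr(cbind(1, x)), V)
  }
  if (any(const_cols)) {
    warning("constant region column(s) set to zero residuals: ",
            paste(colnames(V)[const_cols], collapse = ", "))
    res[, const_cols] <- 0
  }
  dimnames(res) <- dimnames(V)
  out <- thickness_table(res, group_label = table$group_label,
                         subject_ids = table$subject_ids,
                         mean_thickness = table$mean_thickness,
                         check_positive = FALSE)
  attr(out, "adjusted") <- TRUE
  out
}

#' Region-by-region Pearson correlation matrix
#'
#' Correlates every pair of regions across subjects within one group. The
#' diagonal is set to zero (self-connections carry no information in a
#' covariance network). Zero-variance regions get zero rows/columns with a
#' warning.
#'
#' @param table A [thickness_table()] (normally the adjusted one) with at
#'   least 3 subjects.
#' @return An object of class `covariance_matrix` with fields `region_labels`
#'   and `r` (symmetric, `|r| <= 1`, zero diagonal).
#' @export
pearson_matrix <- function(table) {
  stopifnot(inherits(table, "thickness_table"))
  V <- table$values
  if (nrow(V) < 3) stop("correlation requires at least 3 subjects")
  sds <- apply(V, 2, stats::sd)
  zero <- sds == 0
  r <- suppressWarnings(stats::cor(V))
  if (any(zero)) {
    warning("zero-variance region(s) set to zero correlations: ",
            paste(colnames(V)[zero], collapse = ", "))
    r[zero, ] <- 0
    r[, zero] <- 0
  }
  r[!is.finite(r)] <- 0
  diag(r) <- 0
  covariance_matrix(r, colnames(V))
}

#' Construct a covariance (correlation) matrix object
#'
#' @param r Symmetric numeric matrix with entries in `[-1, 1]` and zero
#'   diagonal.
#' @param region_labels Node labels (default: matrix dimnames).
#' @return An object of class `covariance_matrix`.
#' @export
covariance_matrix <- function(r, region_labels = rownames(r)) {
  r <- as.matrix(r)
  if (is.null(region_labels)) stop("region labels are required")
  stopifnot(nrow(r) == ncol(r), length(region_labels) == nrow(r))
  if (max(abs(r - t(r))) > 1e-12) stop("correlation matrix must be symmetric")
  if (any(abs(r) > 1 + 1e-12)) stop("correlations must lie in [-1, 1]")
  if (any(diag(r) != 0)) stop("diagonal must be exactly zero")
  dimnames(r) <- list(region_labels, region_labels)
  structure(list(region_labels = as.character(region_labels), r = r),
            class = "covariance_matrix")
}

#' @export
print.covariance_matrix <- function(x, ...) {
  rv <- x$r[upper.tri(x$r)]
  cat(sprintf("Covariance matrix: %d regions; r range [%.3f, %.3f], %d positive pairs\n",
              nrow(x$r), min(rv), max(rv), sum(rv > 0)))
  invisible(x)
}

# Deterministic ranking of node pairs: by correlation, descending; ties by
# lexicographic (label_i, label_j). Radix order is locale-independent.
edge_ranking <- function(r, labels) {
  ut <- which(upper.tri(r))
  i <- row(r)[ut]
  j <- col(r)[ut]
  rv <- r[ut]
  o <- order(-rv, labels[i], labels[j], method = "radix")
  list(i = i[o], j = j[o], r = rv[o])
}

# Number of edges realized at density d among n nodes (round half away from
# zero, as densities are positive).
edge_count_at_density <- function(d, n) {
  as.integer(round_half_up(d * n * (n - 1) / 2))
}

#' Binarize a correlation matrix at a connection density
#'
#' Keeps the `round(d * P)` most positive correlations (`P = N(N-1)/2` node
#' pairs, rounding half away from zero) as edges. Ranking is by signed
#' correlation — connectivity is grounded in positive morphometric
#' correlations — with ties broken deterministically by region-label order.
#' If the requested edge count exceeds the number of positive correlations,
#' the function proceeds but warns that negative correlations were admitted.
#'
#' @param c A [covariance_matrix()].
#' @param density Target density in `(0, 1]`.
#' @return An object of class `adjacency_matrix` with fields `region_labels`,
#'   `a` (binary, symmetric, zero diagonal) and `density`.
#' @export
binarize_at_density <- function(c, density) {
  stopifnot(inherits(c, "covariance_matrix"),
            is_scalar_number(density), density > 0, density <= 1)
  n <- nrow(c$r)
  m <- edge_count_at_density(density, n)
  rk <- edge_ranking(c$r, c$region_labels)
  if (m > sum(rk$r > 0))
    warning(sprintf(
      "density %.3f requires %d edges but only %d positive correlations exist; non-positive correlations admitted",
      density, m, sum(rk$r > 0)))
  adjacency_from_ranking(rk, m, n, c$region_labels, density)
}

adjacency_from_ranking <- function(rk, m, n, labels, density) {
  a <- matrix(0L, n, n)
  if (m > 0) {
    sel <- seq_len(m)
    a[cbind(rk$i[sel], rk$j[sel])] <- 1L
    a[cbind(rk$j[sel], rk$i[sel])] <- 1L
  }
  dimnames(a) <- list(labels, labels)
  structure(list(region_labels = labels, a = a, density = density),
            class = "adjacency_matrix")
}

#' @export
print.adjacency_matrix <- function(x, ...) {
  cat(sprintf("Adjacency matrix: %d nodes, %d edges (density %.3f)\n",
              nrow(x$a), sum(x$a) / 2, x$density))
  invisible(x)
}

#' Binarize at every density of a grid
#'
#' Shares one edge ranking across all densities, so the returned adjacency
#' matrices are nested (the edge set at a lower density is a subset of the
#' edge set at any higher one).
#'
#' @param c A [covariance_matrix()].
#' @param densities Increasing densities in `(0, 1]` (or a [build_density_grid()]
#'   object).
#' @return Named list of `adjacency_matrix` objects.
#' @export
binarize_grid <- function(c, densities) {
  if (inherits(densities, "density_grid")) densities <- densities$densities
  stopifnot(inherits(c, "covariance_matrix"), all(densities > 0),
            all(densities <= 1))
  n <- nrow(c$r)
  rk <- edge_ranking(c$r, c$region_labels)
  out <- lapply(densities, function(d)
    adjacency_from_ranking(rk, edge_count_at_density(d, n), n,
                           c$region_labels, d))
  names(out) <- formatC(densities, format = "f", digits = 2)
  out
}

#' Minimum density yielding a connected network
#'
#' The smallest multiple of `resolution` at which the binarized network forms
#' a single connected component (no fragmentation). Found by walking the edge
#' ranking once with a union-find structure: the rank position of the edge
#' that first connects the graph translates directly into the minimal grid
#' density. Always at most 1 (the complete graph is connected).
#'
#' @param c A [covariance_matrix()] over at least 2 regions.
#' @param resolution Grid resolution for the reported density (default 0.01,
#'   matching two-decimal reporting of minimum densities).
#' @return A density in `(0, 1]`.
#' @export
minimum_connected_density <- function(c, resolution = 0.01) {
  stopifnot(inherits(c, "covariance_matrix"),
            is_scalar_number(resolution), resolution > 0, resolution <= 1)
  n <- nrow(c$r)
  if (n < 2) stop("at least 2 regions are required")
  rk <- edge_ranking(c$r, c$region_labels)
  parent <- seq_len(n)
  find <- function(v) {
    while (parent[v] != v) {
      parent[v] <<- parent[parent[v]]
      v <- parent[v]
    }
    v
  }
  n_comp <- n
  m_star <- length(rk$i)
  for (k in seq_along(rk$i)) {
    ri <- find(rk$i[k]); rj <- find(rk$j[k])
    if (ri != rj) {
      parent[ri] <- rj
      n_comp <- n_comp - 1
      if (n_comp == 1L) { m_star <- k; break }
    }
  }
  kmax <- as.integer(round_half_up(1 / resolution))
  for (k in seq_len(kmax)) {
    d <- k * resolution
    if (edge_count_at_density(d, n) >= m_star) return(round(min(d, 1), 10))
  }
  1
}

#' Build the shared density grid for a pairwise contrast
#'
#' Anchors the grid at the larger of the two groups' minimum connected
#' densities (so neither network is fragmented anywhere on the grid) and
#' steps upward until the upper bound; the upper bound is included only when
#' hit exactly by the step arithmetic.
#'
#' @param d_min_a,d_min_b Minimum connected densities of the two groups.
#' @param step Grid step (default 0.05).
#' @param upper Upper density bound (default 0.5, beyond which graphs
#'   approach a random configuration).
#' @return An object of class `density_grid` with fields `d_min`, `lower`,
#'   `step`, `upper`, `densities`.
#' @export
#' @examples
#' build_density_grid(0.17, 0.11)$densities  # 0.17, 0.22, ..., 0.47
build_density_grid <- function(d_min_a, d_min_b, step = 0.05, upper = 0.5) {
  stopifnot(is_scalar_number(d_min_a), is_scalar_number(d_min_b),
            is_scalar_number(step), step > 0, is_scalar_number(upper))
  if (d_min_a <= 0 || d_min_b <= 0)
    stop("minimum densities must be positive")
  lower <- max(d_min_a, d_min_b)
  if (lower > upper)
    stop(sprintf("grid lower bound %.3f exceeds upper bound %.3f",
                 lower, upper))
  kmax <- floor((upper - lower) / step + 1e-9)
  densities <- round(lower + step * (0:kmax), 10)
  structure(list(d_min = c(a = d_min_a, b = d_min_b),
                 lower = lower, step = step, upper = upper,
                 densities = densities),
            class = "density_grid")
}

#' @export
print.density_grid <- function(x, ...) {
  cat(sprintf("Density grid: %.2f to %.2f in steps of %.2f (%d densities; D_min = %.2f / %.2f)\n",
              min(x$densities), max(x$densities), x$step, length(x$densities),
              x$d_min[["a"]], x$d_min[["b"]]))
  invisible(x)
}
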