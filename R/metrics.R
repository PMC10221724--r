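# Graph-theoretic metrics on binary adjacency matrices.
#
# Degree and clustering are direct adjacency algebra (cheap enough to run
# inside the permutation engine); shortest-path work goes through igraph;
# neighbor-subgraph efficiencies use a small boolean matrix-power BFS that
# avoids per-subgraph graph construction.

as_adj <- function(a) {
  if (inherits(a, "adjacency_matrix")) a <- a$a
  a <- as.matrix(a)
  stopifnot(nrow(a) == ncol(a))
  if (any(a != 0 & a != 1)) stop("adjacency matrix must be binary")
  if (any(diag(a) != 0)) stop("adjacency diagonal must be zero")
  if (max(abs(a - t(a))) != 0) stop("adjacency matrix must be symmetric")
  storage.mode(a) <- "double"
  a
}

as_igraph <- function(a) {
  igraph::graph_from_adjacency_matrix(a, mode = "undirected", diag = FALSE)
}

#' Node degree
#'
#' Number of connections linking each node to the rest of the network
#' (centrality).
#'
#' @param a An [binarize_at_density()] adjacency matrix (or bare binary
#'   matrix).
#' @return Named integer vector, one value per node.
#' @export
node_degree <- function(a) {
  a <- as_adj(a)
  structure(as.integer(rowSums(a)), names = rownames(a))
}

# Nodal clustering from adjacency algebra: diag(A^3) = 2 * triangles(i).
clustering_from_adj <- function(a) {
  k <- rowSums(a)
  a2 <- a %*% a
  tri2 <- rowSums(a2 * a)          # = diag(A^3) = 2 * triangle count
  cc <- ifelse(k >= 2, tri2 / (k * (k - 1)), 0)
  names(cc) <- rownames(a)
  cc
}

#' Clustering coefficient (nodal and global)
#'
#' Nodal clustering is the number of realized links among a node's neighbors
#' divided by the number possible (`2 t_i / (k_i (k_i - 1))`, zero for nodes
#' with fewer than two neighbors); the global coefficient is its arithmetic
#' mean over all nodes (segregation).
#'
#' @param a Adjacency matrix.
#' @return List with `cc_node` (per node) and `cc_glob`.
#' @export
clustering_coef <- function(a) {
  a <- as_adj(a)
  cc <- clustering_from_adj(a)
  list(cc_node = cc, cc_glob = mean(cc))
}

# Finite-distance summaries from an all-pairs distance matrix.
path_summaries <- function(dm) {
  du <- dm[upper.tri(dm)]
  finite <- is.finite(du)
  list(L = if (any(finite)) mean(du[finite]) else NA_real_,
       e_glob = mean(ifelse(finite, 1 / du, 0)),
       n_unreachable_pairs = sum(!finite))
}

#' Characteristic path length and global efficiency
#'
#' Shortest-path distances by breadth-first search. `L` is the mean over
#' reachable (finite) node pairs — unreachable pairs are excluded and counted
#' so that fragmented networks (possible in permutation replicates) keep a
#' finite path length; `e_glob` is the mean inverse distance over all pairs
#' with `1/Inf = 0`, handling disconnection natively (integration).
#'
#' @param a Adjacency matrix over at least 2 nodes.
#' @return List with `L`, `e_glob`, `n_unreachable_pairs`.
#' @export
path_length_and_efficiency <- function(a) {
  a <- as_adj(a)
  if (nrow(a) < 2) stop("at least 2 nodes are required")
  path_summaries(igraph::distances(as_igraph(a)))
}

# All-pairs shortest path lengths of a small binary graph by boolean matrix
# powers; O(m^3 diam) but allocation-light, used for neighbor subgraphs.
dist_small <- function(a) {
  m <- nrow(a)
  d <- matrix(Inf, m, m)
  diag(d) <- 0
  if (m <= 1) return(d)
  reach <- a > 0
  d[reach] <- 1
  cur <- reach + 0
  k <- 1
  while (k < m) {
    cur <- (cur %*% a) > 0
    k <- k + 1
    new <- cur & is.infinite(d)
    diag(new) <- FALSE
    if (!any(new)) break
    d[new] <- k
    cur <- cur + 0
  }
  d
}

local_efficiency_from_adj <- function(a) {
  k <- rowSums(a)
  n <- nrow(a)
  eloc <- numeric(n)
  for (i in seq_len(n)) {
    if (k[i] < 2) next
    nb <- which(a[i, ] > 0)
    sub <- a[nb, nb, drop = FALSE]
    dm <- dist_small(sub)
    du <- dm[upper.tri(dm)]
    eloc[i] <- mean(ifelse(is.finite(du), 1 / du, 0))
  }
  names(eloc) <- rownames(a)
  eloc
}

#' Local efficiency
#'
#' Efficiency of information transfer within each node's neighborhood: the
#' global efficiency of the subgraph induced by the node's neighbors (the
#' node itself excluded), zero for nodes with fewer than two neighbors.
#'
#' @param a Adjacency matrix.
#' @return Named numeric vector, one value in `[0, 1]` per node.
#' @export
local_efficiency <- function(a) {
  a <- as_adj(a)
  local_efficiency_from_adj(a)
}

#' Small-worldness sigma against degree-preserving nulls
#'
#' `sigma = (CC_glob / mean CC_rand) / (L / mean L_rand)` where the null
#' networks preserve the degree sequence exactly, generated by
#' Maslov-Sneppen edge-swap rewiring (budget: `swap_factor * |E|` rewiring
#' trials per null). Values substantially above 1 indicate small-world
#' organization (high segregation at near-random path length).
#'
#' @param a Adjacency matrix; should be connected (a warning is emitted
#'   otherwise and finite-distance path lengths are used).
#' @param n_null Number of null networks (default 20).
#' @param seed Integer seed for the rewiring; the caller's RNG stream is
#'   preserved.
#' @param swap_factor Rewiring trials per edge (default 10).
#' @param null_graphs Optional list of igraph objects to use as the null
#'   ensemble instead of rewiring (testing hook; e.g. the graph itself gives
#'   sigma = 1).
#' @param return_nulls Also return the null ensemble's degree sequences.
#' @return An object of class `small_world` with fields `sigma`, `c_ratio`,
#'   `l_ratio`, `n_null`, `mean_cc_rand`, `mean_l_rand`, `seed`.
#' @export
small_world_sigma <- function(a, n_null = 20, seed = 1, swap_factor = 10,
                              null_graphs = NULL, return_nulls = FALSE) {
  a <- as_adj(a)
  g <- as_igraph(a)
  if (!igraph::is_connected(g))
    warning("graph is fragmented; sigma computed on finite distances only")
  cc_obs <- mean(clustering_from_adj(a))
  l_obs <- path_summaries(igraph::distances(g))$L
  n_edges <- igraph::ecount(g)
  make_null <- function() {
    igraph::rewire(g, igraph::keeping_degseq(niter = max(1, swap_factor * n_edges)))
  }
  nulls <- if (!is.null(null_graphs)) null_graphs else
    with_preserved_seed(seed, replicate(n_null, make_null(), simplify = FALSE))
  cc_rand <- vapply(nulls, function(gn)
    mean(clustering_from_adj(as.matrix(igraph::as_adjacency_matrix(gn)))),
    numeric(1))
  l_rand <- vapply(nulls, function(gn)
    path_summaries(igraph::distances(gn))$L, numeric(1))
  c_ratio <- cc_obs / mean(cc_rand)
  l_ratio <- l_obs / mean(l_rand)
  out <- structure(
    list(sigma = c_ratio / l_ratio, c_ratio = c_ratio, l_ratio = l_ratio,
         n_null = length(nulls), mean_cc_rand = mean(cc_rand),
         mean_l_rand = mean(l_rand), seed = seed),
    class = "small_world")
  if (return_nulls)
    out$null_degrees <- lapply(nulls, function(gn) igraph::degree(gn))
  out
}

#' @export
print.small_world <- function(x, ...) {
  cat(sprintf("Small-worldness: sigma = %.3f (C/C_rand = %.3f, L/L_rand = %.3f; %d nulls)\n",
              x$sigma, x$c_ratio, x$l_ratio, x$n_null))
  invisible(x)
}

GLOBAL_METRICS <- c("cc_glob", "l", "e_glob", "sigma")
NODAL_METRICS <- c("degree", "cc_node", "e_loc")

# Fast path shared by metric_curves() and the permutation engine: residualize,
# correlate, binarize at all densities from one ranking, compute requested
# metrics. `values`/`mean_thickness` are bare matrices/vectors.
group_curves_matrix <- function(values, mean_thickness, densities,
                                global_metrics, nodal_metrics,
                                n_null = 20, seed = 1, swap_factor = 10) {
  n <- nrow(values)
  p <- ncol(values)
  labels <- colnames(values)
  res <- if (stats::sd(mean_thickness) == 0) {
    scale(values, center = TRUE, scale = FALSE)
  } else {
    qr.resid(qr(cbind(1, mean_thickness)), values)
  }
  r <- suppressWarnings(stats::cor(res))
  r[!is.finite(r)] <- 0
  diag(r) <- 0
  rk <- edge_ranking(r, labels)

  nd <- length(densities)
  glob <- matrix(NA_real_, length(global_metrics), nd,
                 dimnames = list(global_metrics, NULL))
  nodal <- lapply(nodal_metrics, function(m)
    matrix(NA_real_, p, nd, dimnames = list(labels, NULL)))
  names(nodal) <- nodal_metrics
  n_unreach <- integer(nd)

  a <- matrix(0, p, p, dimnames = list(labels, labels))
  m_prev <- 0L
  need_dist <- any(c("l", "e_glob") %in% global_metrics)
  for (di in seq_len(nd)) {
    m <- edge_count_at_density(densities[di], p)
    if (m > m_prev) {
      sel <- (m_prev + 1L):m
      a[cbind(rk$i[sel], rk$j[sel])] <- 1
      a[cbind(rk$j[sel], rk$i[sel])] <- 1
      m_prev <- m
    }
    if ("degree" %in% nodal_metrics) nodal$degree[, di] <- rowSums(a)
    if ("cc_node" %in% nodal_metrics || "cc_glob" %in% global_metrics) {
      cc <- clustering_from_adj(a)
      if ("cc_node" %in% nodal_metrics) nodal$cc_node[, di] <- cc
      if ("cc_glob" %in% global_metrics) glob["cc_glob", di] <- mean(cc)
    }
    if (need_dist) {
      ps <- path_summaries(igraph::distances(as_igraph(a)))
      if ("l" %in% global_metrics) glob["l", di] <- ps$L
      if ("e_glob" %in% global_metrics) glob["e_glob", di] <- ps$e_glob
      n_unreach[di] <- ps$n_unreachable_pairs
    }
    if ("e_loc" %in% nodal_metrics)
      nodal$e_loc[, di] <- local_efficiency_from_adj(a)
    if ("sigma" %in% global_metrics) {
      sw <- small_world_sigma(a, n_null = n_null,
                              seed = sub_seed(seed, sprintf("sigma%03d", di)),
                              swap_factor = swap_factor)
      glob["sigma", di] <- sw$sigma
    }
  }
  list(densities = densities, global = glob, nodal = nodal,
       n_unreachable_pairs = n_unreach)
}

#' Metric curves of one group across a density grid
#'
#' Runs the full single-group pipeline — mean-thickness adjustment, Pearson
#' matrix, binarization at every grid density — and evaluates the requested
#' global metrics (`"cc_glob"`, `"l"`, `"e_glob"`, `"sigma"`) and nodal
#' metrics (`"degree"`, `"cc_node"`, `"e_loc"`) at each density.
#'
#' @param table A raw [thickness_table()].
#' @param densities Density grid (numeric vector or [build_density_grid()]).
#' @param global_metrics,nodal_metrics Metric names to evaluate.
#' @param n_null,swap_factor Null-model settings for sigma (see
#'   [small_world_sigma()]).
#' @param seed Seed for the sigma null models.
#' @return An object of class `metric_curves`: `densities`, `global` (metric
#'   x density matrix), `nodal` (list of node x density matrices),
#'   `n_unreachable_pairs` per density.
#' @export
metric_curves <- function(table, densities,
                          global_metrics = c("cc_glob", "l", "e_glob"),
                          nodal_metrics = c("degree", "cc_node", "e_loc"),
                          n_null = 20, seed = 1, swap_factor = 10) {
  stopifnot(inherits(table, "thickness_table"))
  if (inherits(densities, "density_grid")) densities <- densities$densities
  global_metrics <- match.arg(global_metrics, GLOBAL_METRICS,
                              several.ok = TRUE)
  if (length(nodal_metrics))
    nodal_metrics <- match.arg(nodal_metrics, NODAL_METRICS, several.ok = TRUE)
  out <- group_curves_matrix(table$values, table$mean_thickness, densities,
                             global_metrics, nodal_metrics,
                             n_null = n_null, seed = seed,
                             swap_factor = swap_factor)
  out$group_label <- table$group_label
  class(out) <- "metric_curves"
  out
}

#' @export
print.metric_curves <- function(x, ...) {
  cat(sprintf("Metric curves%s: %d densities (%.2f-%.2f)\n",
              if (!is.null(x$group_label))
                sprintf(" for group '%s'", x$group_label) else "",
              length(x$densities), min(x$densities), max(x$densities)))
  if (nrow(x$global) > 0) {
    cat("  global means across densities:\n")
    for (m in rownames(x$global))
      cat(sprintf("    %-8s %.4f\n", m, mean(x$global[m, ])))
  }
  invisible(x)
}

#' Tidy export of metric curves
#'
#' @param x A [metric_curves()] object.
#' @param ... Unused.
#' @return Data frame with columns `group`, `density`, `level`
#'   (global/nodal), `node` (NA for global), `metric`, `value`.
#' @export
as.data.frame.metric_curves <- function(x, ...) {
  rows <- list()
  for (m in rownames(x$global)) {
    rows[[length(rows) + 1L]] <- data.frame(
      group = x$group_label %||% NA_character_, density = x$densities,
      level = "global", node = NA_character_, metric = m,
      value = x$global[m, ], row.names = NULL)
  }
  for (m in names(x$nodal)) {
    mat <- x$nodal[[m]]
    rows[[length(rows) + 1L]] <- data.frame(
      group = x$group_label %||% NA_character_,
      density = rep(x$densities, each = nrow(mat)),
      level = "nodal", node = rep(rownames(mat), length(x$densities)),
      metric = m, value = as.vector(mat), row.names = NULL)
  }
  do.call(rbind, rows)
}
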