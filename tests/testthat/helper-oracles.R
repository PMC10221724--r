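# Independent brute-force oracles for graph metrics, deliberately naive:
# Floyd-Warshall all-pairs distances, double-loop degree, exhaustive
# neighbor-pair clustering, per-node induced-subgraph efficiency.

oracle_distances <- function(a) {
  n <- nrow(a)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[a > 0] <- 1
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

oracle_degree <- function(a) {
  n <- nrow(a)
  deg <- integer(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) if (a[i, j] == 1) deg[i] <- deg[i] + 1L
  }
  deg
}

oracle_clustering <- function(a) {
  n <- nrow(a)
  cc <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(a[i, ] > 0)
    k <- length(nb)
    if (k < 2) next
    links <- 0
    for (u in nb) for (v in nb) if (u < v && a[u, v] > 0) links <- links + 1
    cc[i] <- 2 * links / (k * (k - 1))
  }
  cc
}

oracle_path_metrics <- function(a) {
  dm <- oracle_distances(a)
  du <- dm[upper.tri(dm)]
  fin <- is.finite(du)
  list(L = if (any(fin)) mean(du[fin]) else NA_real_,
       e_glob = mean(ifelse(fin, 1 / du, 0)),
       n_unreachable_pairs = sum(!fin))
}

oracle_local_efficiency <- function(a) {
  n <- nrow(a)
  eloc <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(a[i, ] > 0)
    if (length(nb) < 2) next
    eloc[i] <- oracle_path_metrics(a[nb, nb, drop = FALSE])$e_glob
  }
  eloc
}

# Random labelled binary adjacency matrix (Erdos-Renyi).
random_adjacency <- function(n, p_edge) {
  a <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (stats::runif(1) < p_edge) a[i, j] <- a[j, i] <- 1L
    }
  }
  dimnames(a) <- list(sprintf("n%02d", 1:n), sprintf("n%02d", 1:n))
  a
}

# Random labelled covariance_matrix with distinct off-diagonal entries.
random_covariance <- function(n) {
  x <- matrix(stats::rnorm(4 * n * n), 4 * n, n)
  r <- stats::cor(x)
  diag(r) <- 0
  colnames(r) <- rownames(r) <- sprintf("n%02d", 1:n)
  scnet::covariance_matrix(r)
}

# Small thickness table from a bare matrix.
make_table <- function(values, group = "G", prefix = group) {
  colnames(values) <- sprintf("r%02d", seq_len(ncol(values)))
  rownames(values) <- sprintf("%s_%02d", prefix, seq_len(nrow(values)))
  scnet::thickness_table(values, group_label = group, check_positive = FALSE)
}

# Ring lattice: n nodes, each connected to k nearest neighbors (k even).
ring_lattice <- function(n, k) {
  a <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    for (s in seq_len(k / 2)) {
      j <- ((i - 1 + s) %% n) + 1
      a[i, j] <- a[j, i] <- 1L
    }
  }
  dimnames(a) <- list(sprintf("n%02d", 1:n), sprintf("n%02d", 1:n))
  a
}

toy_cohort_path <- function() {
  system.file("extdata", "toy_cohort.tsv", package = "scnet", mustWork = TRUE)
}
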