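# Delimited readers/writers for subject-by-region tables and network exports.

detect_delim <- function(path) {
  header <- readLines(path, n = 1)
  if (grepl("\t", header)) "\t" else ","
}

#' Read subject-by-region thickness tables
#'
#' Reads a delimited table with columns `subject`, `group`, `mean_thickness`
#' and one column per region (header row = region labels), and splits it by
#' group. Comma and tab delimiters are supported (`"auto"` inspects the
#' header line).
#'
#' @param path File path.
#' @param delim `"auto"`, `"tab"` or `"comma"`.
#' @return Named list of [thickness_table()]s, one per group, in order of
#'   first appearance.
#' @export
read_thickness_tables <- function(path, delim = c("auto", "tab", "comma")) {
  delim <- match.arg(delim)
  sep <- switch(delim, auto = detect_delim(path), tab = "\t", comma = ",")
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("subject", "group", "mean_thickness")
  if (!all(required %in% names(df)))
    stop("input must contain columns: ", paste(required, collapse = ", "))
  region_cols <- setdiff(names(df), required)
  if (length(region_cols) < 2) stop("at least 2 region columns are required")
  groups <- unique(df$group)
  out <- lapply(groups, function(g) {
    sub <- df[df$group == g, , drop = FALSE]
    vals <- as.matrix(sub[, region_cols, drop = FALSE])
    rownames(vals) <- sub$subject
    thickness_table(vals, group_label = g, subject_ids = sub$subject,
                    mean_thickness = sub$mean_thickness)
  })
  names(out) <- groups
  out
}

#' Write thickness tables to one delimited file
#'
#' Inverse of [read_thickness_tables()]: groups are stacked into a single
#' table with `subject`, `group`, `mean_thickness` and region columns.
#'
#' @param tables Named list of [thickness_table()]s.
#' @param path Output path.
#' @param sep Field separator (default tab).
#' @param digits Significant digits to print (default 15, round-trip safe
#'   for practical purposes).
#' @return `path`, invisibly.
#' @export
write_thickness_tables <- function(tables, path, sep = "\t", digits = 15) {
  check_same_regions(tables)
  rows <- lapply(tables, function(t) {
    data.frame(subject = t$subject_ids, group = t$group_label,
               mean_thickness = signif(t$mean_thickness, digits),
               signif(t$values, digits), check.names = FALSE,
               row.names = NULL)
  })
  df <- do.call(rbind, rows)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export an adjacency matrix as an edge list
#'
#' Two-column table of region-label pairs, one row per edge (upper triangle).
#'
#' @param a An `adjacency_matrix`.
#' @param path Output path (TSV).
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(a, path) {
  stopifnot(inherits(a, "adjacency_matrix"))
  idx <- which(upper.tri(a$a) & a$a == 1, arr.ind = TRUE)
  df <- data.frame(region_i = a$region_labels[idx[, 1]],
                   region_j = a$region_labels[idx[, 2]])
  df <- df[order(df$region_i, df$region_j, method = "radix"), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export an adjacency matrix as GraphML
#'
#' @param a An `adjacency_matrix`.
#' @param path Output path (.graphml).
#' @return `path`, invisibly.
#' @export
write_graphml <- function(a, path) {
  stopifnot(inherits(a, "adjacency_matrix"))
  igraph::write_graph(as_igraph(as_adj(a)), path, format = "graphml")
  invisible(path)
}

#' Export a covariance matrix as a labelled square table
#'
#' Full-precision square matrix with region labels as both header and first
#' column.
#'
#' @param c A [covariance_matrix()].
#' @param path Output path (TSV).
#' @return `path`, invisibly.
#' @export
write_covariance_matrix <- function(c, path) {
  stopifnot(inherits(c, "covariance_matrix"))
  df <- data.frame(region = c$region_labels,
                   format(c$r, digits = 17, trim = TRUE, scientific = TRUE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
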