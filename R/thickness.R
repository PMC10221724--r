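#' Subject-by-region thickness table
#'
#' Container for one group's regional morphometry: a subjects x regions
#' matrix of cortical thickness (mm), the group label, subject ids, and the
#' per-subject overall mean thickness used as nuisance covariate. Raw tables
#' must be strictly positive and free of missing values; adjusted tables
#' (residuals, see [adjust_for_mean_thickness()]) are centered and therefore
#' exempt from the positivity check.
#'
#' @param values Numeric matrix, subjects in rows, regions in columns
#'   (column names = region labels).
#' @param group_label Group name.
#' @param subject_ids Unique subject identifiers (default: row names).
#' @param mean_thickness Per-subject overall mean thickness (default: row
#'   means of `values`).
#' @param check_positive Enforce strictly positive values (TRUE for raw
#'   thickness).
#' @return An object of class `thickness_table`.
#' @export
thickness_table <- function(values, group_label,
                            subject_ids = rownames(values),
                            mean_thickness = rowMeans(values),
                            check_positive = TRUE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(colnames(values)) || anyDuplicated(colnames(values)))
    stop("values must carry unique region labels as column names")
  if (anyNA(values)) stop("thickness values must not contain missing values")
  if (check_positive && any(values <= 0))
    stop("thickness values must be strictly positive (mm)")
  if (is.null(subject_ids))
    subject_ids <- sprintf("%s_%02d", group_label, seq_len(nrow(values)))
  subject_ids <- as.character(subject_ids)
  if (length(subject_ids) != nrow(values) || anyDuplicated(subject_ids))
    stop("subject_ids must be unique, one per row")
  mean_thickness <- as.numeric(mean_thickness)
  if (length(mean_thickness) != nrow(values) || anyNA(mean_thickness))
    stop("mean_thickness must hold one finite value per subject")
  rownames(values) <- subject_ids
  structure(
    list(group_label = as.character(group_label)[1],
         subject_ids = subject_ids,
         region_labels = colnames(values),
         values = values,
         mean_thickness = mean_thickness),
    class = "thickness_table")
}

#' @export
print.thickness_table <- function(x, ...) {
  adj <- isTRUE(attr(x, "adjusted"))
  cat(sprintf("Thickness table: group '%s', %d subjects x %d regions%s\n",
              x$group_label, nrow(x$values), ncol(x$values),
              if (adj) " (adjusted for mean thickness)" else ""))
  cat(sprintf("  mean thickness: %.3f (sd %.3f) mm\n",
              mean(x$mean_thickness), stats::sd(x$mean_thickness)))
  invisible(x)
}

#' @export
dim.thickness_table <- function(x) dim(x$values)

# Check two or more tables share an identical, identically ordered region set.
check_same_regions <- function(tables) {
  ref <- tables[[1]]$region_labels
  for (t in tables[-1]) {
    if (!identical(t$region_labels, ref))
      stop("all groups must share identical, identically ordered region labels")
  }
  invisible(ref)
}
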