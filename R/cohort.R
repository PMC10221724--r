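#' Desikan-Killiany cortical region labels
#'
#' The 68 cortical parcels of the Desikan-Killiany atlas (34 per hemisphere),
#' prefixed `lh_` / `rh_`. These are the default node labels of every network
#' built by the package.
#'
#' @return Character vector of length 68.
#' @export
#' @examples
#' head(dk_regions())
dk_regions <- function() {
  base <- c(
    "bankssts", "caudalanteriorcingulate", "caudalmiddlefrontal", "cuneus",
    "entorhinal", "frontalpole", "fusiform", "inferiorparietal",
    "inferiortemporal", "insula", "isthmuscingulate", "lateraloccipital",
    "lateralorbitofrontal", "lingual", "medialorbitofrontal", "middletemporal",
    "paracentral", "parahippocampal", "parsopercularis", "parsorbitalis",
    "parstriangularis", "pericalcarine", "postcentral", "posteriorcingulate",
    "precentral", "precuneus", "rostralanteriorcingulate",
    "rostralmiddlefrontal", "superiorfrontal", "superiorparietal",
    "superiortemporal", "supramarginal", "temporalpole", "transversetemporal"
  )
  c(paste0("lh_", base), paste0("rh_", base))
}

#' Default contiguous module assignment
#'
#' Splits `n_regions` label positions into contiguous blocks (8 blocks for the
#' full 68-region atlas, fewer for small toy parcellations). The blocks play
#' the role of covariance communities in the synthetic cohort model.
#'
#' @param n_regions Number of regions.
#' @return Integer vector of module ids, one per region.
#' @export
default_module_assignment <- function(n_regions) {
  stopifnot(is_scalar_number(n_regions), n_regions >= 2)
  n_regions <- as.integer(n_regions)
  k <- if (n_regions >= 32L) 8L else max(2L, min(8L, n_regions %/% 2L))
  sizes <- rep(n_regions %/% k, k)
  extra <- n_regions %% k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  rep(seq_len(k), times = sizes)
}

# Block-constant correlation matrix: rho_within inside modules, rho_between
# across, unit diagonal.
block_correlation <- function(modules, rho_within, rho_between) {
  p <- length(modules)
  R <- matrix(rho_between, p, p)
  for (m in unique(modules)) {
    idx <- modules == m
    R[idx, idx] <- rho_within
  }
  diag(R) <- 1
  R
}

# Which blocks of a block-structured correlation matrix fail PSD?
# Returns character(0) when the full matrix is PSD.
offending_blocks <- function(R, modules, tol = 1e-8) {
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) >= -tol) return(character(0))
  bad <- character(0)
  for (m in unique(modules)) {
    idx <- modules == m
    evb <- eigen(R[idx, idx, drop = FALSE], symmetric = TRUE,
                 only.values = TRUE)$values
    if (min(evb) < -tol) bad <- c(bad, as.character(m))
  }
  if (length(bad) == 0) bad <- "between-module structure"
  bad
}

#' Configure a synthetic morphometry cohort
#'
#' Defines the generative model for seeded synthetic cohorts: per region,
#' thickness = baseline mean + a shared global factor (the nuisance that the
#' mean-thickness adjustment later removes) + a block-correlated regional
#' deviation. Regional deviations are multivariate normal with standard
#' deviation `noise_sd` and a block-constant correlation structure
#' (`rho_within` inside modules, `rho_between` across; each component
#' decomposes into a module-shared signal plus independent regional noise).
#' Per group, `group_effects` multiplies the within-module correlation,
#' which is how a group-specific loss of network segregation is injected.
#'
#' @param n_subjects_per_group Subjects per group (default 21).
#' @param n_regions Number of cortical regions (default 68).
#' @param region_labels Unique region labels; defaults to [dk_regions()] when
#'   `n_regions` is 68, else `r01, r02, ...`.
#' @param module_assignment Module id per region; defaults to
#'   [default_module_assignment()].
#' @param rho_within Correlation within modules, in `[0, 1)`.
#' @param rho_between Correlation between modules, in `[0, 1)`, at most
#'   `rho_within`.
#' @param global_factor_sd Standard deviation (mm) of the shared
#'   mean-thickness factor added to every region.
#' @param noise_sd Regional standard deviation (mm) around the baseline.
#' @param group_effects Named per-group multiplier on `rho_within`, in
#'   `[0, 1]`. The names define the groups and their generation order.
#' @param baseline_mean Per-region mean thickness in mm (scalar or length
#'   `n_regions`).
#' @param seed Integer seed; identical configs regenerate identical cohorts.
#' @return An object of class `cohort_config`.
#' @export
#' @examples
#' cfg <- cohort_config(n_subjects_per_group = 10, n_regions = 8, seed = 1)
#' cohort <- generate_cohort(cfg)
#' names(cohort)
cohort_config <- function(n_subjects_per_group = 21,
                          n_regions = 68,
                          region_labels = NULL,
                          module_assignment = NULL,
                          rho_within = 0.5,
                          rho_between = 0.1,
                          global_factor_sd = 0.1,
                          noise_sd = 0.15,
                          group_effects = c(HC = 1, SZND = 1, SZD = 1),
                          baseline_mean = 2.5,
                          seed = 1) {
  stopifnot(is_scalar_number(n_subjects_per_group), n_subjects_per_group >= 1,
            is_scalar_number(n_regions), n_regions >= 2,
            is_scalar_number(rho_within), is_scalar_number(rho_between),
            is_scalar_number(global_factor_sd), is_scalar_number(noise_sd),
            is_scalar_number(seed))
  n_regions <- as.integer(n_regions)
  if (is.null(region_labels)) {
    region_labels <- if (n_regions == 68L) dk_regions() else
      sprintf("r%02d", seq_len(n_regions))
  }
  if (length(region_labels) != n_regions || anyDuplicated(region_labels))
    stop("region_labels must be ", n_regions, " unique strings")
  if (is.null(module_assignment))
    module_assignment <- default_module_assignment(n_regions)
  if (length(module_assignment) != n_regions)
    stop("module_assignment must have one entry per region")
  if (rho_within < 0 || rho_within >= 1 || rho_between < 0 || rho_between >= 1)
    stop("rho_within and rho_between must lie in [0, 1)")
  if (rho_between > rho_within)
    stop("rho_between (", rho_between, ") must not exceed rho_within (",
         rho_within, ")")
  if (global_factor_sd < 0) stop("global_factor_sd must be nonnegative")
  if (noise_sd <= 0) stop("noise_sd must be positive")
  if (is.null(names(group_effects)) || anyDuplicated(names(group_effects)))
    stop("group_effects must be a named vector with unique group labels")
  if (any(group_effects < 0 | group_effects > 1))
    stop("group_effects multipliers must lie in [0, 1]")
  baseline_mean <- rep_len(baseline_mean, n_regions)
  if (any(baseline_mean <= 0)) stop("baseline_mean must be positive (mm)")

  cfg <- structure(
    list(n_subjects_per_group = as.integer(n_subjects_per_group),
         n_regions = n_regions,
         region_labels = as.character(region_labels),
         module_assignment = module_assignment,
         rho_within = rho_within, rho_between = rho_between,
         global_factor_sd = global_factor_sd, noise_sd = noise_sd,
         group_effects = group_effects, baseline_mean = baseline_mean,
         seed = as.integer(seed)),
    class = "cohort_config")

  # PSD is guaranteed when rho_between <= group_effect * rho_within; validate
  # the general case and name the offending block otherwise.
  for (g in names(group_effects)) {
    R <- block_correlation(module_assignment, group_effects[[g]] * rho_within,
                           rho_between)
    bad <- offending_blocks(R, module_assignment)
    if (length(bad) > 0)
      stop("implied correlation matrix for group '", g,
           "' is not positive semi-definite (offending block: ",
           paste(bad, collapse = ", "), ")")
  }
  cfg
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  groups: %s (n = %d each)\n",
              paste(names(x$group_effects), collapse = ", "),
              x$n_subjects_per_group))
  cat(sprintf("  regions: %d in %d modules\n", x$n_regions,
              length(unique(x$module_assignment))))
  cat(sprintf("  rho_within = %g, rho_between = %g, group effects: %s\n",
              x$rho_within, x$rho_between,
              paste(sprintf("%s=%g", names(x$group_effects), x$group_effects),
                    collapse = ", ")))
  cat(sprintf("  global_factor_sd = %g mm, noise_sd = %g mm, seed = %d\n",
              x$global_factor_sd, x$noise_sd, x$seed))
  invisible(x)
}

#' Closed-form covariance of the generated regional values
#'
#' Covariance (about the baseline mean) implied by a [cohort_config()] for one
#' group: `noise_sd^2 * R_g + global_factor_sd^2 * J`, where `R_g` is the
#' block-constant correlation matrix with the group's effective within-module
#' correlation and `J` the all-ones matrix contributed by the shared global
#' factor. Used to validate the generator against its own model.
#'
#' @param config A [cohort_config()].
#' @param group Group label (a name of `config$group_effects`).
#' @return `n_regions x n_regions` covariance matrix.
#' @export
latent_covariance <- function(config, group) {
  stopifnot(inherits(config, "cohort_config"))
  if (!group %in% names(config$group_effects))
    stop("unknown group '", group, "'")
  R <- block_correlation(config$module_assignment,
                         config$group_effects[[group]] * config$rho_within,
                         config$rho_between)
  S <- config$noise_sd^2 * R +
    config$global_factor_sd^2 * matrix(1, config$n_regions, config$n_regions)
  dimnames(S) <- list(config$region_labels, config$region_labels)
  S
}

#' Generate a seeded synthetic cohort
#'
#' Draws one thickness table per group under the model described in
#' [cohort_config()]. The same configuration (including seed) always
#' regenerates identical tables; the caller's RNG stream is left untouched.
#'
#' @param config A [cohort_config()].
#' @return Named list of [thickness_table()] objects, one per group.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_subjects_per_group
  p <- config$n_regions
  with_preserved_seed(config$seed, {
    out <- lapply(names(config$group_effects), function(g) {
      R <- block_correlation(config$module_assignment,
                             config$group_effects[[g]] * config$rho_within,
                             config$rho_between)
      z <- MASS::mvrnorm(n, mu = rep(0, p), Sigma = R)
      if (n == 1L) z <- matrix(z, nrow = 1L)
      gf <- stats::rnorm(n, 0, 1) * config$global_factor_sd
      vals <- matrix(config$baseline_mean, n, p, byrow = TRUE) + gf +
        config$noise_sd * z
      colnames(vals) <- config$region_labels
      rownames(vals) <- sprintf("%s_%02d", g, seq_len(n))
      thickness_table(vals, group_label = g)
    })
    names(out) <- names(config$group_effects)
    out
  })
}
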