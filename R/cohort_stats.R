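# Descriptive cohort comparisons computable from printed summary moments
# (group sizes, means, standard deviations, category counts).

#' One-way ANOVA from group summary statistics
#'
#' `F = [sum n_g (m_g - m_bar)^2 / (G - 1)] / [sum (n_g - 1) s_g^2 /
#' sum (n_g - 1)]`, with the grand mean weighted by group size; equivalent to
#' the ANOVA on any raw data having exactly those moments.
#'
#' @param n,mean,sd Numeric vectors of group sizes (each at least 2), means
#'   and standard deviations.
#' @return List with `statistic` (F), `df` (between, within), `p.value`.
#' @export
#' @examples
#' anova_from_summary(n = c(21, 21, 21), mean = c(40, 39.95, 39.86),
#'                    sd = c(11.5, 11.4, 11.6))
anova_from_summary <- function(n, mean, sd) {
  stopifnot(length(n) == length(mean), length(n) == length(sd),
            length(n) >= 2)
  if (any(n < 2)) stop("each group needs at least 2 observations")
  if (any(sd < 0)) stop("standard deviations must be nonnegative")
  G <- length(n)
  grand <- sum(n * mean) / sum(n)
  ms_between <- sum(n * (mean - grand)^2) / (G - 1)
  ms_within <- sum((n - 1) * sd^2) / sum(n - 1)
  if (ms_within == 0) stop("zero pooled variance; F is undefined")
  f <- ms_between / ms_within
  df <- c(G - 1, sum(n) - G)
  list(statistic = f, df = df,
       p.value = stats::pf(f, df[1], df[2], lower.tail = FALSE))
}

#' Pooled two-sample t-test from group summary statistics
#'
#' Equal-variance (pooled) Student t with `df = n_a + n_b - 2`; the pooled
#' form is identified by the degrees of freedom conventionally reported
#' alongside it.
#'
#' @param n_a,mean_a,sd_a First group's size (at least 2), mean, sd.
#' @param n_b,mean_b,sd_b Second group's size, mean, sd.
#' @return List with `statistic` (t), `df`, `p.value` (two-sided).
#' @export
#' @examples
#' t_from_summary(21, 338.5, 302.5, 21, 484.3, 900.5)
t_from_summary <- function(n_a, mean_a, sd_a, n_b, mean_b, sd_b) {
  stopifnot(is_scalar_number(n_a), is_scalar_number(n_b), n_a >= 2, n_b >= 2,
            sd_a >= 0, sd_b >= 0)
  sp2 <- ((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2) / (n_a + n_b - 2)
  if (sp2 == 0) stop("zero pooled variance; t is undefined")
  t <- (mean_a - mean_b) / sqrt(sp2 * (1 / n_a + 1 / n_b))
  df <- n_a + n_b - 2
  list(statistic = t, df = df,
       p.value = 2 * stats::pt(abs(t), df, lower.tail = FALSE))
}

#' Pearson chi-square test on a groups-by-categories count table
#'
#' Classical Pearson chi-square of independence (no continuity correction),
#' `df = (rows - 1)(cols - 1)`. Rejects tables with a zero row or column
#' marginal, where expected counts are undefined.
#'
#' @param counts Nonnegative integer matrix, groups in rows, categories in
#'   columns.
#' @return List with `statistic`, `df`, `p.value`.
#' @export
#' @examples
#' chi_square_counts(rbind(HC = c(17, 4), SZND = c(17, 4), SZD = c(17, 4)))
chi_square_counts <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("zero row or column marginal; expected counts undefined")
  res <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p.value = unname(res$p.value))
}
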