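---
title: "Structural covariance network analysis: model, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural covariance network analysis: model, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scnet)
```

## The analysis in one paragraph

A structural covariance network treats cortical regions as nodes and the
across-subject Pearson correlation of a morphometric measure — here, regional
cortical thickness — as the basis for edges. Because such networks exist only
at the group level (one correlation matrix per group, not per subject), group
differences cannot be tested subject-wise; instead, subjects are permuted
between groups and the entire network construction is repeated under each
relabeling. `scnet` implements this pipeline end to end: per-region
adjustment for overall mean thickness, group correlation matrices, density
thresholding to binary graphs across a grid of connection densities, graph
metrics along the grid, and a permutation test of a functional summary
statistic integrated over the density range.

## Pipeline assumptions

Three assumptions are inherited from common practice in thickness-based
covariance analysis and are baked into the defaults:

1. **Positive correlations indicate connectivity.** Edges are the largest
   *signed* correlations, not the largest absolute ones. Requesting a
   density so high that non-positive correlations must be admitted is
   allowed but warned about, never silent.
2. **Overall mean thickness is a nuisance.** Each region is residualized by
   ordinary least squares (intercept + slope) on the subject's overall mean
   thickness, within each group, before correlating. Residualization is the
   only adjustment computable from the stated inputs; if the covariate is
   constant the function falls back to mean-centering, and a constant region
   column yields a zero residual column — both with warnings.
3. **Topology should be compared at matched density, not matched threshold.**
   Thresholding different groups at one correlation value yields networks of
   different density, which confounds every metric; the package therefore
   binarizes both groups at the same sequence of densities.

## Density grid

For each group the *minimum connected density* is the smallest multiple of
`resolution` (default 0.01, matching two-decimal reporting) at which the
thresholded network forms a single connected component. It is found exactly,
by walking the edge ranking once with a union–find structure: the rank of
the edge that first connects the graph converts directly into the smallest
grid density realizing at least that many edges. A pairwise contrast is then
evaluated on the grid anchored at the *larger* of the two groups' minima,
stepping by 0.05 up to 0.5 (graphs approach a random configuration beyond
half density); the upper bound is included only when the step arithmetic
hits it exactly.

Numerical conventions worth stating:

- The edge count at density $d$ among $N$ nodes is $\mathrm{round}(d\,P)$
  with $P = N(N-1)/2$, rounding half *away from zero* (base R's banker's
  rounding would make edge counts depend on parity).
- Ties in the correlation ranking are broken lexicographically by region
  label pair, so permutation replicates are bit-reproducible even with tied
  values.
- Because the connectivity criterion is applied to the *rounded* edge count,
  the minimum connected density can be one grid step below the naive ratio
  `(edges needed)/P` — e.g. nine spanning-tree edges out of 45 pairs are
  already realized at density 0.19, since round(45 × 0.19) = 9.
- The contrast grid is fixed from the observed groups and reused for every
  permutation replicate (the same thresholding procedure applied to each
  randomized group); minima are not re-estimated per replicate.

## Graph metrics

On each binary graph the package evaluates centrality (degree), segregation
(nodal clustering $CC_{node} = 2t_i/(k_i(k_i-1))$, zero for degree < 2, and
its mean $CC_{glob}$), and integration (characteristic path length $L$,
global efficiency $E_{glob}$, local efficiency $E_{loc}$ = global efficiency
of the neighbor-induced subgraph with the node removed). Two conventions
handle fragmentation, which permutation replicates can produce below the
observed minimum density:

- $L$ averages *finite* distances only, and the count of unreachable pairs
  is carried in every result rather than discarded;
- $E_{glob}$ needs no convention: $1/\infty = 0$.

Small-worldness is
$\sigma = (CC_{glob}/\overline{CC}_{rand}) / (L/\overline{L}_{rand})$
against an ensemble (default 20) of degree-preserving Maslov–Sneppen
rewirings with a budget of `swap_factor * |E|` rewiring trials (default 10
per edge; igraph counts attempted trials, rejecting swaps that would create
loops or multi-edges). Sigma is the costliest metric by two orders of
magnitude — each permutation replicate would itself need a full null
ensemble per density — so the package supports it inside
`scn_permutation_test()` but the worked analyses evaluate it on the observed
group networks and permutation-test the cheaper metrics; users who need a
permutation p-value for sigma can request it and budget accordingly.

On nested binarizations (shared edge ranking across densities) clustering
and local efficiency rise with density overall, but neither is guaranteed
monotone step by step — an added edge can inflate a node's degree faster
than it closes triangles, typically near the sparse end of the grid. The
test suite asserts exactly that documented behavior: a dominant rise with at
most small, infrequent dips.

## The functional comparison

A metric evaluated along the density grid is a curve, and comparing curves
pointwise would multiply tests across densities. The functional statistic
used here is the trapezoidal integral of the between-group difference curve
divided by the grid span — the *mean functional difference*, sign preserved.
Integrating first and testing once accounts for the density range by
construction. A single-density grid (possible when the lower anchor reaches
the upper bound) degenerates gracefully to the plain difference.

The permutation scheme reassigns whole subjects (their full regional vector
plus mean thickness) to two groups of the original sizes, recomputing the
*entire* pipeline — including the mean-thickness adjustment, which is a
group-level operation — within each permuted group. The two-tailed p-value
is the plus-one percentile estimator
$p = (1 + \#\{|T^{perm}| \ge |T^{obs}|\})/(n_{perm} + 1)$,
which cannot return zero at finite $n_{perm}$ and returns exactly 1 for
identical groups. Subjects are pooled in sorted-id order before permuting,
so swapping the order of the two groups negates the observed statistic while
leaving the null distribution — and hence the p-value — identical for
equal-sized groups.

Nodal tests are corrected across the density range by construction but *not*
across the 68 nodes, mirroring standard reporting of this design;
`node_fdr = TRUE` adds a Benjamini–Hochberg column for users who want the
across-node correction.

## What the synthetic cohorts emulate — and what they do not

No subject-level morphometry ships with the package; `generate_cohort()`
produces seeded cohorts with the statistical structure the analysis assumes.
Per region $j$ and subject $i$:

$$x_{ij} = \mu_j + g_i + \varepsilon_{ij}, \qquad
  g_i \sim N(0, \sigma_g^2), \qquad
  \varepsilon_{i\cdot} \sim N(0, \sigma^2 R)$$

where $R$ is block-constant: correlation `rho_within` inside contiguous
modules, `rho_between` across them, so each regional deviation decomposes
into a module-shared signal plus independent noise. The shared factor $g_i$
is exactly the global-thickness nuisance the adjustment step removes. A
per-group multiplier on `rho_within` (`group_effects`) injects a loss of
within-module covariance — the generative analogue of reduced network
segregation. Positive semi-definiteness holds by construction whenever
`rho_between` ≤ effective `rho_within`; the constructor validates the
general case and names the offending block otherwise.

Defaults are chosen once to represent realistic study conditions: 21
subjects per group and 68 Desikan–Killiany regions (the reference design for
this analysis family); baseline thickness 2.5 mm with regional standard
deviation 0.15 mm and a 0.1 mm global factor (typical cortical-thickness
scales); `rho_within` 0.5 and `rho_between` 0.1 (moderate correlations of
the size published covariance communities show); eight contiguous modules;
all group multipliers 1, so the default cohort is a *null* cohort, and
perturbation experiments state their effect explicitly.

The generator emulates block-structured covariance, a shared nuisance
factor, and group-specific segregation deficits. It does **not** emulate
spatial autocorrelation on the cortical sheet, hemispheric asymmetries,
distance-dependent connectivity, segmentation or motion artifacts,
age/sex structure, or site effects. Passing tests on synthetic cohorts
therefore demonstrate statistical correctness and calibration of the
pipeline, not robustness to the failure modes of real MRI morphometry.

Effect sizes on the thickness scale are free parameters of the generator,
not calibrated to any particular patient population.

## Problem sizes used by the shipped analyses

The test suite and the reproduction script run at sizes chosen to exercise
the full design while remaining comfortable on a laptop core: calibration
uses 200 null datasets × 99 permutations (a rejection-rate standard error of
about 0.015 at the nominal 0.05 level); the recovery experiment uses 20
replicates × 199 permutations at the default 21 subjects per group; the
showcase three-group analysis uses 199 permutations per contrast. For a
publication-grade analysis of real data, 1000 permutations per contrast is
the conventional setting (`n_perm = 1000`, the package default).

## Known limitations

- Binary graphs only; weighted covariance networks are out of scope.
- The functional statistic is the normalized signed area: a difference that
  changes sign across the density range can partially cancel. This matches
  the integrated-difference design but users probing crossing curves should
  inspect the per-density curves (`plot()` on the comparison object).
- Sigma's null ensemble size (20) trades precision for cost; ratios based on
  few nulls are noisy for very sparse graphs, where rewiring also mixes
  poorly.
- Group-level networks mean group-level inference: no subject-level network
  statistics are available by design.
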