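---
title: "Partitioning community mean size change: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning community mean size change: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleosize)
```

## The scientific problem

A community's mean trait value — here, the mean diameter of dinoflagellate
cysts in a sediment assemblage — can change between two climate periods
through two mechanisms that have very different ecological interpretations.
Species can change size themselves (intraspecific change, phenotypic
plasticity under the temperature–size rule), or the community can reorganise
so that larger or smaller species gain relative abundance (interspecific
change, species turnover). Most paleoecological size reconstructions assign
each taxon a fixed literature size and therefore see only the second
mechanism. `paleosize` computes both, from two inputs:

* an **observation table** of individually measured cyst diameters
  (`species`, `period`, `diameter` in μm), and
* an **assemblage table** of counted cysts per species and period
  (`species`, `period`, `count`), which defines relative abundances.

## The model

For each period, the community-weighted mean including both sources of
change weights each measured cyst by its species' assemblage share spread
evenly over that species' measurements:

$$\bar{x}_{intra+inter} = \frac{\sum \varnothing_{obs} \, w_{obs}}{\sum w_{obs}},
\qquad w_{obs} = \frac{w_{spe}}{m_{spe}}, \qquad w_{spe} = \frac{N_{spe}}{N},$$

with $\varnothing_{obs}$ an individual diameter, $m_{spe}$ the number of
measured cysts of the species in the period, $N_{spe}$ its assemblage count
and $N$ the period's total count over the included species. Observation
weights sum to 1 by construction. The mean excluding intraspecific change
fixes each species at a cross-period species mean $\varnothing_{avg}$:

$$\bar{x}_{inter} = \frac{\sum \varnothing_{avg} \, w_{spe}}{\sum w_{spe}},$$

which varies between periods only through the weights. Writing $\Delta$ for
comparison-minus-reference differences (cold minus warm in the motivating
design),

$$\Delta\bar{x}_{intra} = \Delta\bar{x}_{intra+inter} - \Delta\bar{x}_{inter}$$

is an exact identity: the two components always sum to the total, for any
input. `decompose_size_change()` reports the deltas and their signed
fractions of the total; when the total change is exactly zero the fractions
are undefined and reported as `NA` rather than zero.

Key modelling assumptions:

* **Cyst diameter proxies cell size 1:1**, so diameter changes translate
  directly to the motile population.
* **Within-species sizes are approximately normal**; normality is assessed
  visually via `histogram_data()` overlays, not tested formally.
* **The included species represent the community.** Weights are
  renormalised over the species present in both tables, so unidentifiable
  and rare taxa are excluded and the "community" is the measured subset.

## Weighted statistics and tests

* `wtd_mean()` is the standard ratio estimator, invariant to uniform weight
  rescaling.
* `wtd_sd()` uses $\sqrt{\frac{\sum w(x-\bar{x}_w)^2}{\sum w}\cdot\frac{n}{n-1}}$.
  The $n/(n-1)$ small-sample factor is a deliberate convention (exposed as
  `correct = TRUE`): it makes the equal-weight case coincide exactly with
  the ordinary sample SD, so per-species rows and community rows are on the
  same footing. `correct = FALSE` gives the plain weighted population form.
* **Effective sample size.** SEs are $sd/\sqrt{n}$ with $n$ = number of
  measured cysts at the observation level but $n$ = number of species at
  the interspecific level, where each species contributes one trait value.
  This is the only convention under which the two community SE cells of the
  motivating study's summary table (5.97/√219 = 0.40 and 6.60/√6 = 2.69)
  are reproduced.
* `welch_test()` / `welch_test_summary()` implement the unequal-variance
  two-sample t-test with Welch–Satterthwaite degrees of freedom; two-sided
  p-values throughout, and no multiple-testing correction across the
  per-species battery (six tests), matching the study design the package
  mirrors.
* `weighted_welch_test()` uses
  $t = (\bar{x}_{w,b}-\bar{x}_{w,a})/\sqrt{SE_a^2+SE_b^2}$. Its reference
  source gives the statistic but no degrees of freedom; we apply
  Satterthwaite to the weighted variance components $s_w^2/n$ with
  component dfs $n-1$ (default), because it reduces exactly to the ordinary
  Welch test under uniform weights — a property the test suite checks to
  machine precision. `df_mode = "pooled"` ($n_a+n_b-2$) is exposed for
  sensitivity analysis; with community-scale $n$ the two are practically
  indistinguishable.

## The cross-period species mean

"Mean size of each species across both periods" is ambiguous. The default,
`pooling = "pooled"`, averages all of a species' measured cysts over both
periods, so period sample sizes act as weights; `pooling = "period_mean"`
gives both periods equal weight regardless of sampling effort. We default to
pooling because the raw measurement set is the primary object — each cyst is
one observation of the species — but without the original raw data neither
convention can be adjudicated against the published interspecific means, so
both are exposed.

## Literature comparison

Taxonomic keys report some taxa as diameter ranges and others as length ×
width ranges. `lw_to_diameter()` converts the latter by endpoint-wise
averaging, and `range_midpoint()` takes the middle of a range. Both round
**half away from zero** to integers (50.5 → 51, 34.5 → 35, 23.5 → 24);
banker's rounding would disagree on exact halves, and the away-from-zero
rule reproduces every derived cell of the bundled literature table. The rule
is stated explicitly so other implementations can match bit-for-bit.
`compare_species()` flags, by strict inequality, means outside the
literature range and measured ranges extending beyond it.
`literature_community_mean()` evaluates the interspecific mean with
midpoints as the fixed trait values and the *same* per-period assemblage
weights as the measured interspecific mean — the only internally consistent
choice, since the literature supplies trait values, not abundances.

## The synthetic-data generator

No raw measurement table was ever deposited for the motivating study, so the
package ships a generator whose defaults are the study conditions:

* six species × two periods with the published per-species means, SDs and
  measurement counts (448 cysts in total: 219 warm, 229 cold);
* assemblage totals of 613 (warm) and 680 (cold) counted cysts;
* dominant-species abundance fractions at the published values
  (*I. minutum* 0.50→0.65, *P. dalei* 0.20→0.08, *I.? cezare* 0.04→0.06).

The three minor species' fractions were never published; the fixture
allocates each period's remainder (0.26 warm, 0.21 cold) to them
proportionally to their measured n and renormalises. This is a **declared
fixture convention, not a reconstructed value** — consequently the package
does not claim to reproduce the study's absolute community means, only the
structure of the analysis (under the fixture weights the expected
intraspecific fraction is about 0.8, and the test suite checks that the
Monte-Carlo mean over 200 seeds stays within 0.60–0.85). The "Other"
category of rare and unidentifiable cysts is excluded and weights
renormalised over the six measured species, since measurements exist only
for those six and community weights must sum to 1 over included cysts.

Diameters are drawn from a normal distribution truncated below at 0.1 μm.
Truncation exists only to guarantee positivity; at realistic parameter
values (means 20–50 μm, SDs 3–7 μm) the truncated mass is below 1e-8 and the
draw is numerically a plain normal. A zero-SD spec yields a point mass —
useful for exact-arithmetic tests.

**Seeding.** One integer seed drives everything. Per-(species, period)
substream seeds are derived from it in sorted key order, so the values
generated for a given species do not depend on the row order of the
configuration — reordering specs permutes rows but never changes a single
diameter. The generator restores R's global RNG state on exit.

**Assemblage counts** are apportioned by the largest-remainder method: each
species starts at `floor(fraction × total)` and the leftover units go to the
largest fractional parts (ties broken toward the more abundant species).
This conserves per-period totals exactly *and* keeps every count within one
cyst of its exact value `fraction × total`. The naive alternative — round
every count and push the residual onto the dominant species — can displace
the dominant species' count by several cysts when the minor species happen
to round in the same direction, which in the default fixture it does.

What the generator does **not** emulate: any generative link from
temperature to size (sizes are drawn at the fixed per-period parameters),
spatial or within-period stratigraphic structure, preservation/taphonomic
bias, measurement error distinct from population variance, and non-normal
size distributions. Passing tests therefore show that the analysis machinery
recovers the parameters of a normal, well-mixed world; they cannot validate
the method against, e.g., skewed size distributions or correlated sampling.

## Numerical and degenerate-input choices

* All-zero weights, zero assemblage totals, and two zero-variance samples in
  a Welch test raise classed errors (`paleosize_degenerate_error`) rather
  than returning NaN.
* Fewer than two observations per (species, period) is an error in
  summaries; single-species community rows report `NA` dispersion.
* A species with assemblage weight but no measurements is dropped with a
  warning and the remaining weights renormalised (so observation weights
  still sum to 1); a measured species with no assemblage count is an error.
* Histogram bins are left-closed `[k·w, (k+1)·w)` aligned to multiples of
  the bin width, so halving the width refines bins exactly; the default
  width of 2 μm resolves the 3–7 μm within-species SDs without emptying most
  bins at n ≈ 20–60 per group. Normal overlay ordinates are scaled to count
  units, `n · w · φ(mid)`.
* Report CSVs are written at full precision; rounding to printed precision
  happens only in documentation and the acceptance summary.

## Problem sizes used in the checks

The test suite runs entirely on synthetic data built in code: the default
fixture (448 observations per seed), 200-seed Monte-Carlo loops for the
parameter-recovery checks, a 1000-seed loop for the generator's
standard-error calibration at one species, an SD-convergence check at
n = 10⁴, and a ×400-scale run (≈180k draws) for generator–summariser
consistency, where each species mean must land within 0.5% of its target —
at that scale the band is about four standard errors wide, so the check has
essentially no false-alarm probability while remaining sensitive to real
bias. All checks complete in seconds on one core.

## Known limitations

* Two periods only; the partition generalises to gradients and multiple
  periods, but this implementation deliberately mirrors a two-period
  contrast design.
* No bootstrap or analytical confidence interval on the decomposition
  fractions.
* Exact string matching of species names (after whitespace trimming):
  synonymy between cyst-based and vegetative names must be resolved in the
  input files.
* The weighted Welch test's degrees of freedom at the interspecific level
  rest on n = 6 "observations"; with so few species the test is honest but
  weak, which is intrinsic to species-level inference, not to the
  implementation.
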