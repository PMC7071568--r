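---
title: "Methods: weighted group comparison of allele frequencies across UVB environments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: weighted group comparison of allele frequencies across UVB environments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uvbclines)
```

## The analysis model

The package asks a simple question with careful bookkeeping: do the
variant-allele frequencies of candidate variants differ between cohorts of
European (EUR), East Asian (EAS) and Sub-Saharan African (AFR) ancestry, and
do the group means line up with the long-term UVB environment of each
group's region?

The unit of analysis throughout is the **sample set** — one population
cohort with a group label, a subject count $n$, and a location. Working at
the cohort level (rather than pooling subjects) keeps heterogeneous data
sources on a common footing: an allele-frequency database row and a
sequencing panel both reduce to "one frequency, one cohort size, one place".
Cohort sizes enter as weights everywhere, so a 107-subject panel moves the
group mean more than an 8-subject isolate, without letting it erase the
isolate entirely.

For one variant with per-set frequencies $y_i$, weights $w_i = n_i$ and
groups $g(i)$, the engine computes a weighted one-way ANOVA:

$$\mathrm{SSB} = \sum_g W_g (\bar y_g - \bar y)^2, \qquad
  \mathrm{SSW} = \sum_i w_i (y_i - \bar y_{g(i)})^2,$$

with $W_g$ the group weight totals and all means weighted. Then
$F = \frac{\mathrm{SSB}/(k-1)}{\mathrm{SSW}/(N-k)}$,
$r^2 = \mathrm{SSB}/(\mathrm{SSB}+\mathrm{SSW})$ and adjusted
$r^2 = 1-(1-r^2)\frac{N-1}{N-k}$. This is algebraically identical to
weighted least squares of $y$ on group indicators, which the test suite
asserts against `stats::lm(..., weights =)` to $10^{-10}$: association $p$
and $r^2$ from "least squares regression" and from "ANOVA" are the same
object here, which is why a single engine serves both descriptions.

The implicit variance model of weighted least squares is
$\operatorname{Var}(y_i) \propto 1/w_i$: larger cohorts are assumed to
estimate their population frequency more precisely. That is exactly right
for binomial sampling noise and only approximately right when real
between-population drift dominates (see the generator section for what this
means for calibration).

### Post hoc comparisons, letters, thresholds

All-pairs comparisons use the Tukey–Kramer studentized-range statistic
$q_{ij} = |\bar y_i - \bar y_j| \big/ \sqrt{\tfrac{\mathrm{MSW}}{2}
\left(\tfrac{1}{W_i}+\tfrac{1}{W_j}\right)}$ with
$\mathrm{MSW} = \mathrm{SSW}/(N-k)$ and the group weight totals on the same
weighted scale as MSW. Studentized-range probabilities come from base R's
`ptukey`, the same primitive behind `TukeyHSD`; the suite cross-checks the
balanced equal-weight case against `TukeyHSD` on `aov` fits and the $k=2$
case against the pooled $t$-test ($q = t\sqrt 2$, identical $p$).

Significance uses Bonferroni-adjusted thresholds, strict inequality:
association $p < 0.001$, pairwise $p < 10^{-4}$ by default (both
configurable via `significance_thresholds()`). A $p$ exactly at the
threshold is not significant. In the limit `alpha_pairwise -> 0` no pair is
ever called significant and every variant classifies as `NONE`; the suite
exercises this limiting case.

The compact letter display is an insert-and-absorb assignment (start with
one letter covering all groups; for each significant pair split every letter
containing both members; absorb subsets), processed in the fixed order EUR,
EAS, AFR so output is deterministic. For three groups letter sharing is
exactly equivalent to pairwise non-significance, which the suite verifies on
1000 random $p$ matrices straddling the threshold.

### Confidence intervals

Group CIs are model-based, from the pooled MSW rather than per-group
standard deviations:
$\bar y_g \pm t_{N-k,\,0.975}\sqrt{\mathrm{MSW}\,\bar w / W_g}$, with
$\bar w$ the mean weight over the sets used. Pooling is what lets a group
whose observed frequencies are all zero still carry a positive-width
interval — hence lower bounds below zero, which are deliberately not clamped
to $[0,1]$: the interval describes the model's uncertainty about a mean, not
the support of a frequency. The $\bar w$ factor places MSW (which lives on
the weighted scale, units of $w \cdot y^2$) back on the response scale using
the design's average cohort size as the reference weight. This scaling is a
convention; the tests cover the interval's shape (symmetry about the mean,
monotone widening with level, degeneracy at $\mathrm{MSW}=0$), not its
width against any external table.

### Pattern and cline labels

The three pairwise flags map exhaustively onto six labels: all three
significant → `ALL_DIFFER`; exactly two significant → the group common to
both significant pairs `*_DIFFERS`; exactly one → `PARTIAL`; none → `NONE`.
`PARTIAL` has no counterpart in the usual three-group footnote taxonomy; it
is named explicitly rather than forced into a neighbouring label.

The UVB-cline label orders the three group means by ascending group mean
annual UVB (derived from the raster comparison, or supplied explicitly) and
checks strict monotonicity of the point estimates. No trend test is run —
the label is descriptive, matching how such clines are usually narrated —
and ties yield `NONE`.

## Variant selection and ancestry validation

Variants are ranked by fixation index, descending, with ties broken by rsID
so selection is invariant to input order. The kept set is the top
`top_fraction` of the ranking (cut at `ceiling(top_fraction * n)`, so at
least one variant always survives) intersected with `fst >= fst_floor`
(defaults 0.30 and 0.13), minus any excluded function classes (default
`Unknown`). Each exclusion carries one reason code (`BELOW_FLOOR` takes
precedence over `BELOW_RANK`, then `FUNCTION_CLASS`), making filtering
decisions auditable. Database-provided fixation indices in the annotation
table take precedence over recomputed ones, mirroring how such catalogues
are used in practice; when absent, `fst_by_variant()` computes Wright's
frequency-variance form either across all sample sets or across pooled
group frequencies — both modes exist because catalogues rarely document
which they used.

Ancestry validation checks cohort-weighted group means of three
pigmentation markers: the derived alleles of rs1426654 and rs16891982 must
be near-fixed in EUR (mean $\ge 0.90$) and near-absent elsewhere
($\le 0.10$), and rs1800414 must sit in the intermediate East Asian window
(0.50–0.65, a window widened slightly above the commonly quoted 0.50–0.60
so that a weighted mean of 0.62 from large panels does not fail the group).
Note the "fixed in Europeans" criterion is a *minimum* of 0.90 — thresholds
are configurable, and the defaults encode the intended direction. Sample
sets lacking data for any marker are excluded from the whole analysis (with
a warning and a manifest entry), since groups cannot be validated on
cohorts that cannot be checked.

## UVB aggregation

The raster is daily noontime 305 nm surface irradiance (mW/m²/nm) on a
regular half-degree grid, cells addressed by centre (offsets of 0.25°). A
point location belongs to the cell containing it, with boundary ties going
north/east (equivalently: `floor(x / 0.5) * 0.5 + 0.25`). A cohort recorded
as a latitude *range* contributes every cell whose centre latitude falls in
the closed range, at the cohort's longitude cell — with `range_mode =
"midpoint"` available to use one representative cell instead, since either
reading of "cells within sample set locations" is defensible; the manifest
records which was used. Mean annual UVB per set is the plain arithmetic mean
of all daily values over all selected cells (order-invariant and linear in
the raster, both tested). Group comparison reuses the weighted ANOVA engine
with the per-set means as responses.

A set without coordinates (the built-in roster contains one, a cohort whose
latitude was never published) is excluded from UVB aggregation only — it
keeps contributing to frequency statistics.

## The synthetic generator

`simulate_sample_sets()` draws, for each set in group $g$ and variant with
group mean $p_g$, a latent frequency from the Balding–Nichols model
$\mathrm{Beta}\!\left(p\frac{1-\theta}{\theta},
(1-p)\frac{1-\theta}{\theta}\right)$, whose expected differentiation across
sets equals $\theta$ — giving an analytic link between the dispersion knob
and the fixation indices the pipeline estimates, which is what makes
parameter-recovery tests possible. $\theta < 10^{-9}$ and $p \in \{0, 1\}$
degenerate to exactly $p$. Observed frequencies default to the latent draw
(`observation = "latent"`), keeping analytic checks exact; binomial mode
divides a draw of $2n$ alleles by $2n$ when sampling noise is wanted.

The defaults are the study design the package is built around:

- the 60-cohort roster (`table6_sample_sets()`): 18 EUR / 24 EAS / 18 AFR
  sets with published cohort sizes (972 / 795 / 866 subjects; 7–116 per
  cohort) and latitudes (EUR 36–75° N, EAS 21–53° N, AFR 29° S–23° N);
- generative group means from the published production/transport-locus
  table plus the three pigmentation markers (`default_group_means()`);
- $\theta = 0.02$, the dispersion at which pattern-recovery behaviour is
  assessed;
- a raster surface $\max(0,\; 92 - 1.4\,|\mathrm{lat}|)$ mW/m²/nm with
  day-to-day Gaussian noise (sd 2), truncated at zero. Base and decay were
  chosen once so the roster's three groups land near the observed group
  means of ~82 / ~48 / ~18 mW/m²/nm, and the monotone decay guarantees the
  AFR > EAS > EUR ordering for any roster whose AFR band is nearest the
  equator.

What the generator does *not* emulate: within-group substructure ($\theta$
is a single scalar per collection, so Finnish and Sardinian cohorts are
exchangeable), linkage between variants (draws are independent across
rsIDs), temporal selection dynamics, and any realistic geography in
longitude (the roster's longitudes are synthetic representative values; the
raster depends on latitude only, so they are inert). Passing tests therefore
demonstrate that the machinery is correct and calibrated under a drift-only
model — not that real data meet that model's assumptions.

One calibration subtlety is worth stating plainly: under Balding–Nichols the
between-set variance is $\theta p(1-p)$ for every set, regardless of cohort
size, while the weighted ANOVA assumes variance $\propto 1/w_i$. With the
published (unequal) cohort sizes the null distribution of the weighted $F$
is therefore only approximate. The null-calibration check consequently uses
equal cohort sizes ($n = 100$, 20 sets per group, $\theta = 0.05$), where
the weighted analysis reduces exactly to the classical one; there the
empirical type-I error at $\alpha = 0.05$ sits within $\pm 0.02$ of nominal
over 2000 replicates. With real designs the weighting is a variance
*model*, and strongly heteroskedastic drift can make it approximate — a
known limitation of cohort-weighted analyses generally.

## Numerical choices and degenerate inputs

- All responses equal: $F = 0$, $p = 1$, $r^2 = 0$. Zero within-group
  variance with real between-group spread: perfect separation, $p = 0$,
  flagged on the fit object.
- $\mathrm{MSW} = 0$: degenerate CIs (zero width) and pairwise $p \in
  \{0, 1\}$ by whether the means differ.
- Wright's estimator returns 0 for a monomorphic pooled frequency and is
  clamped to $[0,1]$; Weir–Cockerham estimates are truncated at 0 for
  reporting with the raw value kept in an attribute, and return `NA` when
  $a+b+c = 0$ (no information). Single-diploid populations contribute no
  among-individual component.
- Frequencies are validated to $[0,1]$ at every ingestion point; the only
  missing token is `NA`, and missing cells drop a set from that variant
  only, with per-variant set/subject counts recording what was used.
- Report rendering: means and CIs at 2 decimals, $p$ values in scientific
  notation with 3 significant digits; reading a written report back
  reproduces values at rendered precision.
- Reproducibility: generator functions take an explicit seed, restore the
  caller's RNG state, and identical seeds yield byte-identical end-to-end
  reports.

## Test problem sizes

The suite runs the full 60-set design end to end; Monte-Carlo components
use 2000 replicates for null calibration, 200 replicates for
parameter recovery, 100 random instances for the Weir–Cockerham
cross-check, 1000 random $p$ matrices for the letter display, and five
seeded runs (median) for pattern recovery — sizes chosen to make the checks
stable from run to run while keeping the default suite quick on a laptop.

## Known limitations

- The frequency table must already be oriented to the designated variant
  allele; the package performs no strand or allele reconciliation between
  sources and documents this as an input contract.
- The CI width convention (pooled MSW scaled by the mean weight) is one of
  several defensible choices; comparisons across packages should rely on
  the $p$ values and letters, which are convention-free.
- Cline labels are descriptive monotonicity checks, not trend tests.
- No linkage-disequilibrium or haplotype structure is modelled or used;
  variants are analysed marginally.
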