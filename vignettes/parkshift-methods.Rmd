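---
title: "Methods: projecting climate-driven assemblage change in protected areas"
author: "parkshift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: projecting climate-driven assemblage change in protected areas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(parkshift)
```

## The problem

Species distribution models (SDMs) score every grid cell of a landscape with
an environmental suitability value in [0, 1] — how well conditions there
explain a species' presence — together with a species-specific occurrence
threshold above which the species is treated as present. Given such surfaces
for a baseline period and for a warming scenario, a protected-area manager
wants to know: which species is each park likely to gain or lose, how much
will its assemblage turn over, and will the assemblage's *functional*
composition (the spread of traits it contains) contract or expand?

`parkshift` implements that analysis chain for any set of congruent suitability
surfaces, park masks and trait tables. It does **not** fit SDMs: baseline and
scenario surfaces are consumed as input.

## Per-cell change classification

For each cell, presence in a period means suitability at or above the
threshold. The transition between periods is classified as:

* **potential extirpation** — present in the baseline, absent under the
  scenario;
* **potential colonisation** — the reverse;
* otherwise, both present, by percent change
  $\Delta = 100\,(s_{\mathrm{scen}} - s_{\mathrm{base}})/s_{\mathrm{base}}$:
  **worsening** for $\Delta \in [-100, -25)$, **stable** for
  $\Delta \in [-25, +25]$, **improving** for $\Delta > +25$;
* cells below threshold in both periods carry a bookkeeping category
  **absent**.

Two boundary conventions are deliberate. First, the published category bounds
overlap at ±25%; we resolve both endpoints to *stable* (conservative toward
no-change), and compute $\Delta$ in double precision with no rounding before
the interval test. Second, *absent* cells are excluded from the park majority
vote below: structural zeros would otherwise drown the signal in large parks,
and a species occupying a single corner of a park would never receive a
projection.

## Park summaries, presence rules and review filters

A park's projection for a species and season is the category with the largest
cell count over the park mask (cells are counted whole; masks are sets of
0-based row-major cell indices). Ties are broken by a fixed, configurable
priority — extirpation > colonisation > worsening > improving > stable —
deterministic and biased toward flagging change for management triage. A
species whose park cells are all *absent* gets no record.

Presence follows from the majority: a species is present now if the majority
is extirpation/worsening/stable/improving, and present in the future if it is
worsening/stable/improving/colonisation.

Because suitability marks *potential* rather than confirmed occurrence,
expert review enters as a flag table. `unconfirmed_baseline` flags (species
never confirmed at the park: transients, migrants, accidentals) drop the
record entirely unless its majority is a colonisation, which has no baseline
presence to remove (warning). `improbable_colonisation` flags (e.g. a
dispersal-limited species projected across a continent) remove
colonisation-majority records only; on any other majority the flag is
incompatible and warns without removing. Filtering operates at species x park
x season granularity, and the run report records the fraction of records each
flag class removed.

## Assemblage metrics

Per park and season, the current and future presence sets A and B give
species richness, colonisation and extirpation counts, and turnover as one
minus Sorensen similarity $2|A \cap B|/(|A|+|B|)$ (Jaccard turnover is
reported alongside; it always dominates Sorensen). Turnover is undefined and
flagged NA when both sets are empty.

Parks are placed in five relative trend groups from the scatter of
colonisation proportion (scaled by future richness) against extirpation
proportion (scaled by current richness) — the denominators are configurable
because published analyses of this design do not state theirs. With per-axis
medians and upper quartiles (linear-interpolation quantiles, type 7):

* *high turnover*: both proportions high;
* *high potential colonisation* / *extirpation*: exactly one high;
* *low change*: both strictly below the medians;
* *intermediate change*: the remainder.

"High" means at or above the upper quartile **and** strictly above the
median. The extra clause is our boundary convention: it keeps the five
sectors exhaustive and mutually exclusive and sends fully degenerate inputs
(all parks identical) to *intermediate change* rather than declaring every
park high-turnover. Parks with no colonisations or extirpations at all are
still classified (they land in *low change*). At least 5 parks per season are
required for quartiles to mean anything.

Regional summaries report mean ± SE (sample SD over √n parks) of richness
change, colonisations, extirpations and turnover per region and season plus a
national row; single-park regions print a bare mean (SE `NA`).

## Functional trait space

Species carry five traits — feeding behavior, primary food type, preferred
habitat, nesting behavior (unordered categories) and relative size (ordered
levels). Gower distance averages per-trait contributions: 0/1 mismatch for
categories, range-scaled absolute rank difference for the ordered trait
(equally spaced ranks; the encoding is ours, as published analyses rarely
state theirs). A single-level column contributes 0 for every pair but stays
in the five-trait denominator, with a warning.

The space is a principal coordinates analysis (PCoA) of the distance matrix.
Gower matrices are generally non-Euclidean, so dissimilarities are
square-root transformed first (the standard correction; configurable to
`"none"`); if fewer than `n_axes` positive eigenvalues remain the embedding
fails loudly rather than silently patching eigenvalues. Six axes are the
default, matching common practice for presence-based functional analyses.
Embedding quality is summarized by the mean squared deviation (mSD) between
the input dissimilarities and the reduced-space distances rescaled so their
maxima agree; 0 is a perfect embedding, and mSD shrinks as axes are added.

Per season, one space is built from the pooled species of both periods —
current and future indices must live in a common space to be comparable.

* **Functional richness (FRic)**: convex-hull volume of the assemblage
  divided by the pool's hull volume. Hull volumes come from an exact
  supporting-hyperplane facet enumeration written for this package (compiled
  code; exponential in dimension, exact at the tens-of-species scales used
  here, validated against closed-form polytopes and independent 2-D/3-D
  oracles). Assemblages with fewer than `n_axes + 1` affinely independent
  species have no hull and are flagged `insufficient_species` rather than
  given a fake zero.
* **Functional dispersion (FDis)**: mean distance of members to their
  unweighted centroid (presence-absence data, so no abundance weights),
  scaled by half the pool's largest pairwise distance — the dispersion of an
  assemblage holding only the two most distant species. The scaled value can
  legitimately exceed 1 (an equilateral triangle of side $d$ scores
  $2/\sqrt 3 \approx 1.155$) and is deliberately not clamped.
* **Taxon restrictedness (TRes)**: the fraction of parks a species occupies,
  0 = absent everywhere, 1 = present everywhere. Note the direction: 1 means
  *no* restriction, which inverts the usual convention of the index this
  summary descends from; we implement the stated direction. Only species
  present in at least one park in **both** periods are scored; the maximum
  dispersion pair and the pool are taken per season, not globally.

Parks that would distort the functional analyses (in the motivating study,
high-Arctic parks and one offshore island) are handled by a configurable
exclusion list, never hard-coded geography.

## Model II major-axis regression

Future index values are regressed on current ones across parks (or species,
for TRes). Both axes are the same quantity measured with error, so ordinary
least squares would attenuate the slope; the major axis — the first
principal axis of the joint scatter, minimizing perpendicular distances — is
the appropriate model II fit. With sample (co)variances $s_{xx}, s_{yy},
s_{xy}$:

$$b = \frac{s_{yy} - s_{xx} + \sqrt{(s_{yy} - s_{xx})^2 + 4 s_{xy}^2}}{2 s_{xy}},
\qquad a = \bar y - b \bar x.$$

The slope CI uses the classical angle bound: with covariance eigenvalues
$\lambda_1 \ge \lambda_2$,
$H = F_{1-\alpha;1,n-2} \big/ \big[(\lambda_1/\lambda_2 +
\lambda_2/\lambda_1 - 2)(n-2)/4\big]$ and the limits are
$\tan(\arctan b \pm \tfrac12 \arcsin \sqrt H)$; $H \ge 1$ means the data do
not constrain the axis direction at that level and the interval is reported
unbounded. The intercept CI propagates through the means. A perfect fit
yields zero-width intervals.

Significance is two-fold, mirroring how such tables are usually starred: a
permutation test of association (999 permutations of y against x by default,
two-tailed on |r|, $p = (1 + \#\{|r^\ast| \ge |r|\})/(n_{\mathrm{perm}}+1)$)
and departure from the 1:1 null judged by the CIs excluding slope 1 or
intercept 0. A permutation test naturally tests association, not slope = 1,
so both are reported and neither is conflated with the other. The RNG seed
is part of the configuration and recorded in the run report.

## The synthetic landscape generator

Real continental SDM surfaces are neither shippable nor desk-scale, so the
generator emulates their statistical structure with known ground truth:

* a purely latitudinal environmental gradient (cell row), the simplest
  geometry that produces colonisation at the leading edge and extirpation at
  the trailing edge;
* Gaussian niches: baseline suitability
  $\exp(-(r - \mu_i)^2 / 2w^2)$ for species $i$ with optimum $\mu_i$ drawn
  uniformly over rows (independently per season), niche breadth $w$
  (`response_width`, default 6 rows);
* the scenario displaces the gradient north by `shift_cells` rows (default
  6), so noise-free scenario suitability at row $r$ equals baseline at
  $r - k$;
* i.i.d. Gaussian noise (`noise_sd`, default 0.05) clipped to [0, 1] — the
  simplest perturbation that keeps the ground-truth oracle tractable;
* one shared occurrence threshold (default 0.35) for all synthetic species
  (the pipeline supports per-species thresholds; a single value keeps the
  oracle simple);
* parks as disjoint axis-aligned rectangles (3–5 cells a side) placed in a
  block partition of the grid — unambiguous masks with no geometry
  dependencies — each labelled with a latitude-tercile region;
* a five-trait table sampled uniformly over realistic level sets, and review
  flags sampled at 17% (unconfirmed baseline) and 3.2% (improbable
  colonisation) of records, the removal rates reported by expert screening
  of continental bird SDM output.

The default grid is 40 x 30 cells with 30 species and 8 parks: large enough
that every pipeline stage (including 6-axis hulls) runs on meaningful inputs,
small enough that the brute-force oracle and the full test suite complete in
seconds. Everything is deterministic given the config seed.

The generator also produces ground truth: `oracle_assemblages()`
re-derives every park's category table by exhaustive per-cell enumeration
with scalar arithmetic, sharing no code with the vectorised pipeline. Tests
require exact agreement on dozens of random landscapes.

What the generator does **not** emulate: spatial autocorrelation of noise,
longitude-dependent structure, species interactions, GCM ensembles, or real
park geometry. Passing tests therefore demonstrate the correctness of the
*computations*, not the realism of any particular projection.

## Numerical choices and degenerate inputs

* Quantiles: linear interpolation (`type = 7`) everywhere.
* Percent change: double precision, no rounding before interval tests;
  baseline-below-threshold cells never reach the ratio.
* Hull volumes: relative tolerance 1e-9 on supporting-hyperplane tests;
  duplicated species coordinates are deduplicated; coplanar facets (common
  with categorical traits) are handled exactly by recursive projection.
* Empty assemblages: parks with no records for a season are omitted with a
  warning; both-empty turnover is NA; species absent everywhere in a period
  are dropped from restrictedness with a warning.
* MA regression: isotropic scatter with zero covariance has no defined axis
  and errors; constant x or y errors; eigenvalue ratios below 1e-12 are
  treated as a perfect fit (zero-width CIs).
* All pipeline randomness (permutation tests) flows from the single config
  seed; rerunning a config byte-reproduces every output file, which the test
  suite checks with checksums.

## Worked example

```{r example, eval = FALSE}
d <- generate_landscape(landscape_config(seed = 1))
cfg <- pipeline_config(output = "parkshift-demo", seed = 1)
report <- run_pipeline(cfg, dataset = d)
report
read.csv(file.path("parkshift-demo", "regression_table.csv"))
```

The run writes six tables (projections, trend groups, regional summary,
functional indices, restrictedness, regression table) plus `run_report.json`
with record counts, removal fractions, warnings and output checksums.

## Known limitations

* FRic is undefined for assemblages smaller than `n_axes + 1` affinely
  independent species; with the desk-scale demo and 6 axes this affects many
  parks (they are flagged, and the regression then uses the defined parks).
  Real species pools of hundreds of species rarely hit this.
* The hull algorithm is exponential in the number of axes; beyond ~8 axes or
  hundreds of unique pool coordinates a dedicated qhull binding would be the
  right tool.
* Turnover, trend sectors and scaled dispersion all depend on documented
  conventions (denominators, boundary rules, per-season pools) that published
  studies leave unstated; all are surfaced as configuration rather than
  claimed as reconstructions.
* No resampling: all surfaces must share one grid. Resampling policy changes
  analyses and is out of scope.
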