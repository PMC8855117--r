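---
title: "Morphotype discovery and allele-size association: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphotype discovery and allele-size association: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(astromorph)
```

`astromorph` implements a complete analysis chain for a comparative
question in avian neurobiology: whether hippocampal astrocytes form
discrete morphological classes (morphotypes) and whether microsatellite
allele size at a candidate locus covaries with migratory distance across
shorebird species.  This vignette is the package's account of the methods
themselves — the models, their assumptions, the tunable parameters, and
the places where the design was genuinely open and a choice had to be
made.

## Reconstructions and stereological sampling

Cells enter as rooted trees of measured nodes (SWC interchange format;
coordinates and radii in micrometres).  The tree invariants — one root,
parents before children, unique ids, positive radii — are enforced by
`validate_tree()`, which enumerates violations instead of failing on the
first.

Two pre-processing steps mirror common histological practice:

* **Z shrinkage** (`correct_z_shrinkage()`, default factor 1.75).
  Dehydration collapses a section along the cutting axis while barely
  affecting the section plane, so every `z` is multiplied by the factor
  and `x`, `y` and radii are untouched.  Whether a published factor means
  "multiply recorded z" or "divide nominal thickness" is often left
  implicit; this package multiplies the recorded coordinate, restoring
  pre-processing thickness.  The two conventions differ only by using
  `1/factor`.
* **Probe-grid selection** (`place_probe_grid()`, `select_cells()`).
  Square probes (side 50 µm) sit on a lattice with 900 µm spacing whose
  origin is a seeded uniform random offset in `[0, spacing)²` —
  systematic-random sampling, making the expected probe count
  proportional to the region's area.  Probe boxes use half-open
  `[lo, hi)` inclusion on both axes so abutting boxes can never select
  the same soma twice, and a probe containing no soma falls back to the
  single nearest outside soma (Euclidean distance to the box, ties broken
  by lowest `cell_id` for determinism).

## The 19 morphometric variables

`compute_features()` produces, per cell: total branch length; tortuosity
(mean per-segment arc/chord ratio); segment and branch-point counts and
segments per mm; base diameter of primary branches (twice the radius of
the first node after the soma, averaged over primaries); frustum-model
tree surface area, per-primary branch surface area, and total branch
volume; mean planar bifurcation angle; 2-D (section-plane projection) and
3-D convex hull perimeter/area/surface/volume; vertex counts Va/Vb/Vc
(bifurcations with two, one, or zero terminal daughters); box-counting
fractal dimension; and the composite complexity score

$$\text{complexity} = \left(\sum \text{terminal orders} + \#\text{terminals}\right)\times\frac{\text{total branch length}}{\#\text{primary branches}}$$

which couples topological depth to metric extent and is the single most
informative screening variable for astrocyte classes.

Aggregation conventions that the variable names alone do not fix, and the
conventions adopted here:

* *Tortuosity* and *planar angle* are per-cell **means** (over segments
  and over branch points); cells without bifurcations report `NA` for the
  angle rather than 0, since the quantity is undefined.
* *Branch surface area* is the tree surface divided by the number of
  primary branches (mean per primary tree); *tree surface area* is the
  total.
* Edges leaving the soma use the distal node's radius at both frustum
  ends so the soma body does not inflate branch surface/volume.
* The 2-D hull is taken over the XY (section-plane) projection.
* Fractal dimension uses 3-D box counting on the arbor resampled at a
  quarter of the smallest box size, 8 dyadic scales from half the largest
  coordinate extent downward, least-squares slope of
  $\log N(s)$ on $\log(1/s)$, clamped to $[0,3]$.  A straight cable
  measures ≈ 1, a dense planar patch ≈ 2.

These are Euclidean quantities: tests assert invariance under in-plane
rigid motions and the exact homogeneity degrees (length × s, area × s²,
volume × s³) under uniform scaling.

## Screening, transform, clustering

**Multimodality index.**  For each feature the package computes
$\mathrm{MMI} = (M_3^2 + 1)\,/\,(M_4 + 3(n-1)^2/((n-2)(n-3)))$ with
$M_3$ the bias-corrected sample skewness and $M_4$ the bias-corrected
sample *excess* kurtosis (the SAS bimodality-coefficient convention).
Under this convention a large normal sample scores 1/3, a uniform sample
5/9 ≈ 0.555, and a symmetric two-point sample 1 — which is exactly why
0.55 is the canonical screening threshold: features scoring above it are
flatter-than-uniform or skew-split, i.e. plausibly multimodal.  The
screen keeps features with MMI **strictly** greater than 0.55.  If the
kurtosis convention were raw (Pearson) kurtosis instead of excess, the
same formula would put uniform data near 0.3 and the 0.55 threshold would
be meaningless; the excess convention is the one that makes the published
threshold coherent, and the package adopts it.

**Variance-shrunk log transform.**  Selected features are log₁₀
transformed (features containing zeros fall back to `log10(x+1)` and are
flagged) and scaled to unit variance, so that micron-, micron²- and
micron³-scale variables contribute comparably to Euclidean distances.

**Ward clustering and the cut.**  `ward_cluster()` uses Ward's
minimum-variance criterion (`hclust`, `ward.D2`; heights equal
$\sqrt{2\,\Delta SS}$, verified in tests against a naive $O(n^3)$
agglomeration).  The number of morphotypes over `k_range = 2:6` is chosen
at the largest **relative** jump between successive merge heights
(equivalently, the largest gap on log heights).  The absolute-gap rule —
cut where the raw height difference is largest — looks natural but
degenerates for the geometry these data actually have: morphotypes lie
along a complexity gradient, roughly collinear in feature space, and for
collinear, comparably spaced groups the final merge always dominates the
absolute differences, forcing k = 2 regardless of the true class count.
The relative jump compares each between-group merge with the structure
just below it and recovers the generated k for both 3- and 4-class
populations.  `k` can always be fixed explicitly.  Morphotype labels are
renumbered so type 1 is the most complex class, following the field's
convention.

**Discriminant validation.**  Forward stepwise entry on the partial
Wilks F (entry at p < 0.05, no removal step, plus a standard tolerance
guard: candidates whose within-group variance is ≥ 99.99 % explained by
already-entered variables are skipped — without it, the strong
inter-correlation of morphometric variables drives the within-group
scatter singular).  The canonical functions come from the
between/within eigenproblem; reported are eigenvalues, percent variance,
the sequential function tests $\Lambda_k = \prod_{i \ge k} 1/(1+\lambda_i)$
with Bartlett χ² p-values, the structure matrix (pooled within-group
correlations of features with canonical scores), and a resubstitution
confusion table.  Resubstitution (not cross-validation) matches how
classification accuracy is conventionally reported for this design and is
what the package's accuracy figures mean.

**Representative cells and density peaks.**  The "average cell" of a
cluster minimises the summed Euclidean distance to all other members
(ties by lowest id).  Mode counting uses a Gaussian KDE on a 512-point
grid; peaks are interior maxima with topographic prominence above 5 % of
the density maximum.  The default bandwidth is the Sheather–Jones
selector rather than Silverman's rule: Silverman's bandwidth is
calibrated to a unimodal Gaussian reference and scales with the pooled
SD, which for a well-separated mixture exceeds the within-class SD and
merges genuine modes (measured on the default three-class populations it
over-smooths a substantial fraction of seeds even at > 4σ separation).
The bandwidth remains a user argument for anyone wanting the rule-of-thumb.

## Permutation inference

All multivariate tests run on the Euclidean distance matrix of
`log10(x+1)`, unit-variance-scaled features
(`assemble_distance_matrix()`).

* **PERMANOVA** partitions the Gower-centred inner-product matrix over a
  crossed fixed-effects design with type III sums of squares
  (full-minus-reduced fits, sum-to-zero contrasts).  P-values permute the
  residuals of the reduced model excluding the tested term
  (Freedman–Lane on the Gower matrix); a free raw-permutation scheme is
  available and is the default for the univariate allele-size comparison,
  which is a one-way design where the two schemes coincide in their null.
  With Euclidean distances and one factor the pseudo-F reproduces the
  classical ANOVA F exactly (asserted to 1e-9), and the null rejection
  rate is calibrated in the acceptance suite (1000 replicates, 999
  permutations, rate within [0.03, 0.07]).
* **PERMDISP** embeds the distance matrix by principal coordinates
  (negative eigenvalues handled by the imaginary-axis correction),
  computes distances to plain group centroids — no bias correction
  options — and tests their means with the one-way F, permuting the
  least-squares residuals.  The crossed "species × type" dispersion
  question is answered by treating the crossed cells as the grouping,
  which is an interpretation: dispersion homogeneity is defined for a
  single factor, and this is the natural crossed reading.
* **Pairwise pseudo-t** is the square root of the two-group pseudo-F with
  permutation restricted to the pair; raw and Sidak-adjusted p-values are
  both reported.
* The univariate GLM battery reports the one-way F, pairwise t on the
  pooled mean square with Sidak adjustment $1-(1-p)^m$, and Cohen's d
  from the two groups' pooled SD.

Every permutation p-value uses the $(\#\{\ge\} + 1)/(n_{perm}+1)$
convention — never exactly zero — and every result records its seed and
permutation count.

## Microsatellite statistics

Diversity per species: allele count A, private alleles, observed
heterozygosity, and unbiased expected heterozygosity
$\hat H_e = \frac{2n}{2n-1}\left(1 - \sum_i p_i^2\right)$ over the $2n$
gene copies (the convention of the standard population-genetics tools for
this design).  Hardy–Weinberg is tested by Monte-Carlo re-pairing of the
observed gene copies; because the heterozygote count is a small integer,
the two-sided p-value uses the distance from the re-pairing expectation
with a mid-p correction (half weight on ties), which keeps the null
distribution of p close to uniform where plain tail-doubling is visibly
lumpy.  Differentiation uses Weir–Cockerham θ (allele-identity variance
components) for FST and the allele-size ANOVA analogue for RST, without
size standardisation — so RST values are comparable across runs of this
package but not directly to standardised reports; tests assert the
characteristic contrast that FST is invariant to a uniform size shift
while RST is size-based.  The association of allele size with migratory
distance pairs each **individual's mean allele size** (the allele-level
vs individual-level choice is not forced by the design; the individual
mean is the less pseudo-replicated option) with its species' distance
(8039, 9309, 13139 km; 0 km for the resident) and reports midrank
Spearman ρ with a permutation p plus the OLS correlation R.

## The synthetic generators

The morphology generator is a stochastic binary-branching process chosen
for analyzability, not biological realism: a fixed number of primaries
leave the soma in random directions; each segment is a 4-step polyline
whose direction performs a small von-Mises-like random walk (Gaussian
increments, SD `wiggle`), and bifurcates with probability `branch_prob`
until `max_order`.  Radii taper geometrically per order, with ~15 %
lognormal cell-to-cell calibre variability (without it, base diameter is
exactly constant within a class — a degenerate covariance no real
population has).  The default classes are graded in branching probability
(0.2 / 0.5 / 0.8, plus 0.95 for the fourth class), order depth (3–6) and
segment length (15 / 46 / 95 / 220 µm, 10 % SD), with 8–12 primaries;
these values were calibrated once so that the generator meets its stated
contract — pooled complexity and hull volume tri-/quadrimodal, classes
separated clearly enough that the morphotype pipeline can in principle
recover them — and are not revisited per analysis.  What the generator
does **not** emulate: imaging noise, reconstruction errors, within-class
correlations between topology and calibre, spatial interactions between
cells, or the long-tailed class-imbalance of real sections.  Passing the
recovery tests therefore shows the pipeline is correct and well
calibrated on data satisfying its assumptions, not that real astrocyte
populations are this clean.

The genotype generator draws both alleles independently from a
discretised normal on a 2-bp ladder (168–204 bp), so Hardy–Weinberg holds
by construction; the default spec gives four species means rising 4 bp
per distance rank with SD 2 bp and 13 individuals per species, matching
the scale of a typical field collection (12–14 per species), and a flat
variant serves as the no-association control.

All randomness flows from one root seed through a documented Lehmer-step
splitter (`derive_seed()`), so every pipeline stage is independently
reproducible and the whole run is byte-identical under a fixed seed.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run at desk scale, chosen as
the package's own study conditions: populations of 40 cells per class
(120–160 cells), 20 seeds per recovery experiment, 999 permutations
inside calibration loops and the full 9999 for single analyses, 1000
replicates for the PERMANOVA type-I calibration, and 100 seeds for the
association recovery.  Degenerate inputs are handled explicitly: zero
areas and coplanar point sets report zero hull metrics with a flag;
zero-chord segments are excluded from tortuosity with a warning;
constant features are rejected (MMI) or dropped (transform); a singular
within-group scatter falls back to a documented ridge; monomorphic
species return HWE p = 1 and undefined FST as `NA`.  Ties are broken
deterministically (lowest id) wherever a selection could otherwise
depend on row order.

## Known limitations

* The morphotype count is chosen over `k_range = 2:6` from the dendrogram
  geometry; strongly unbalanced or nested class structures may need an
  explicit `k`.
* Stepwise discriminant entry is forward-only with resubstitution
  accuracy; there is no cross-validated error estimate.
* RST is unstandardised; FST assumes diploid, single-locus data.
* PERMANOVA supports crossed fixed factors only — no nested or random
  effects, and no non-Euclidean dissimilarities beyond accepting a
  precomputed symmetric matrix.
* The SWC reader expects one cell per file and does not parse vendor
  formats.
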