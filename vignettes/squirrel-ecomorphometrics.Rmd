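---
title: "Methods: craniodental ecomorphometrics of hybridizing pine squirrels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: craniodental ecomorphometrics of hybridizing pine squirrels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the statistical models implemented in
`sciuromorph`, the assumptions behind them, the tunable parameters and why
their defaults are what they are, and the design decisions taken where the
methodology left genuine choices open.

## The study design

Two parapatric pine squirrels — the Douglas squirrel (*Tamiasciurus
douglasii*, a soft-cone feeder of wet maritime forests) and the red
squirrel (*T. hudsonicus*, a hard-cone feeder of dry continental forests)
— meet and hybridize in a narrow contact zone. The pipeline compares five
groups (allopatric Douglas, hybrid-zone Douglas, hybrids, hybrid-zone red,
allopatric red; `squirrel_groups()`) on three craniodental trait systems
tied to bite force: an incisor-geometry proxy for maximal bite force,
cranial-suture complexity, and mandible shape. Group membership for
hybrid-zone animals comes from genomic admixture proportions Q, with pure
classes at Q ≥ 0.90 (red) and Q ≤ 0.10 (Douglas) and hybrids strictly
between (`classify_admixture()`; thresholds inclusive exactly as stated).

## Bite force quotient

`incisor_strength()` computes the section modulus of an idealized
rectangular incisor cross-section, `Zi = ap² · ml / 6` (mm³). It assumes
the incisor resists biting as a bending beam; it ranks relative biting
ability and is not an in-vivo force in Newtons. `calibrate_bite_force()`
maps it to log10 Newtons through the rodent-wide calibration
`0.566 · log10(Zi) + 1.432`.

`fit_bfq()` removes body-size allometry by regressing log10 force on log10
body mass **within the analyzed sample** and taking residuals (the BFQ).
The regression is deliberately refit per dataset rather than frozen at the
reference coefficients exposed by `bfq_reference_coefficients()`
(0.3849, 0.6970): the quotient is defined relative to the specimens under
study, and the reference fit belongs to a sample that is not available.
Because the calibration is affine in log10 Zi, BFQ equals 0.566 times the
residual of log10 Zi on log10 mass — a useful internal consistency check
that the test suite asserts to 1e-10. Specimens missing mass or incisor
dimensions are retained in the output with `bfq = NA` and a logged count,
never imputed.

Univariate group tests use `trait_ancova()`: ordinary least squares with
sequential (Type I) F-tests, sex as a covariate factor, parametric
p-values (the mainstream choice for univariate ANCOVA), least-squares
adjusted means at covariate means via emmeans, and Holm-corrected
pairwise t-contrasts by default (`posthoc_pairs()`; Tukey-Kramer and
Bonferroni are options). Specimens of unknown sex are excluded from
sex-adjusted models with a logged count.

## Suture complexity

`length_ratio()` is the traced path length over the endpoint chord — 1
for a straight suture, larger for interdigitated ones. It is invariant to
rigid motion, uniform scaling, and polyline refinement, so tracing units
are arbitrary; the package therefore accepts traces in any consistent
units. Curved SVG commands are rejected rather than approximated: any
arc-flattening error should happen upstream, visibly, not inside the
statistic. Coincident endpoints make the chord zero and are an error
("degenerate chord"), as the ratio is undefined.

The five per-suture LRs are analyzed jointly by PCA on the **covariance**
matrix (all five variables share the same dimensionless scale;
correlation-based PCA would equalize sutures with very different
complexity ranges). Side bookkeeping (right side preferred, left when
damaged) is metadata only and never enters the statistic. Interrupted
sutures are an exclusion decided upstream by the analyst — there is no
quantitative interruption detector.

## Geometric morphometrics

`gpa()` performs partial generalized Procrustes superimposition: center,
scale to unit centroid size, rotate to the evolving consensus with the
closed-form 2-D orthogonal Procrustes solution restricted to proper
rotations, iterate to a consensus-change tolerance of 1e-8 (at most 100
iterations). Numerical choices worth stating:

* **Reflections are disallowed** (rotation determinant +1). Mandibles
  photographed from the other side must be flipped during data
  preparation; a reflected configuration will *not* silently match.
* **No tangent-space projection.** Shape variation at this scale is small
  and projection differences are below test tolerances; PCA runs directly
  on Procrustes coordinates.
* Aligned shapes keep unit centroid size; size enters the models as
  log10 centroid size computed from the raw coordinates.
* A zero-size (all points identical) configuration aborts with the
  specimen named.

`bending_energy_matrix()` builds the thin-plate-spline bending-energy
quadratic form from the kernel `U(r) = r² log r²` with the affine block
`[1, x, y]`; the matrix is symmetrized and has exactly three near-zero
eigenvalues spanning affine maps (asserted in tests). Collinear references
make the system singular and error out.

`slide_semilandmarks()` implements bending-energy sliding: per specimen,
semilandmarks move along tangent directions (unit chord between curve
neighbours; endpoint semilandmarks use their single neighbour — chords,
not spline derivatives, because they are simpler and stable for 45
semilandmarks on three curves) by the exact linear least-squares minimizer
of the TPS bending energy relative to the current consensus. Fixed
landmarks never move. After each pass GPA is re-run and the consensus
updated; the default is 3 cycles with per-cycle energy bookkeeping (the
energy never increases within a cycle, by construction). Sliding is
against the consensus, not per-specimen references, and sliding amounts
are unbounded — semilandmarks may travel past curve endpoints; the maximum
slide magnitude per cycle is logged so extreme slides are visible.

One behaviour of this criterion deserves emphasis: smooth tangential
displacement fields along a curve are nearly bending-free, so the exact
minimizer can move semilandmarks of noisy configurations a long way at
negligible energy cost. With isotropic digitization noise this *amplifies*
tangential scatter into smooth, correlated variance modes that can occupy
leading principal components. This is a property of unconstrained
bending-energy sliding, not a defect of the implementation; it is why the
synthetic generator's effect-to-noise defaults are set the way they are
(below).

`morph_pca()` uses the covariance matrix of column-centred data, drops
incomplete rows with their ids logged, orders axes by eigenvalue, and
applies a deterministic sign convention (largest-magnitude loading entry
positive) so results are reproducible across platforms.
`axis_significance()` builds the null by permuting each column within
itself — preserving marginals, destroying covariance — and uses the
add-one permutation p-value `(1 + #{prop* ≥ prop}) / (n_perm + 1)`, so
p-values are in (0, 1] and the smallest attainable value is
`1/(n_perm+1)`.

### Procrustes ANOVA

`procrustes_anova()` decomposes a multivariate response by sequential
(Type I) fits in the stated term order — group, sex, size, group:size,
sex:size, the order of the study design — with the sum of squares of a
term being the trace difference of residual cross-product matrices of the
nested fits. Significance is by residual randomization (RRPP): permute the
reduced-model residuals, add them back to the reduced-model fit, recompute
F. The permutation schedule is shared across terms and seeded. The effect
size Z is the standard deviate of log F within the permuted log F*
distribution (observed included) — the convention of the
residual-randomization literature; the wording "normal quantile of the
permutation position" admits either reading and this one is stable when
p saturates at its minimum. F = 0 yields Z = NA. A term that adds no rank
to the design errors out, naming itself, rather than silently absorbing
zero degrees of freedom.

Whether the shape response should be the full Procrustes coordinates or
the retained PC scores is genuinely open; the pipeline defaults to
PC1 + PC2 scores (the axes the Monte Carlo test retains), and
`procrustes_anova()` accepts any response matrix, so either analysis is a
one-liner. `pairwise_groups()` uses the Euclidean distance between group
mean vectors (the Procrustes distance between mean shapes when the
response is Procrustes coordinates) with label-permutation p-values and
Holm correction.

## Morphospace overlap

`morphospace_overlap()` works in (PC1, PC2, log10 centroid size) — three
dimensions, though any trait count is supported. Each group gets the
conjugate posterior of a multivariate normal under the noninformative
prior |Σ|^−(d+1)/2: Σ inverse-Wishart(n−1, centred cross-products), μ|Σ
normal(sample mean, Σ/n). The overlap of A onto B is the probability that
a draw from A's normal lands in B's α-level Mahalanobis ellipsoid,
estimated by Monte Carlo (membership counting; dimension-agnostic, with
error controlled by `n_mc`). The defaults — 3000 posterior iterations,
10,000 Monte Carlo draws, α = 0.95 — follow the morphospace-overlap
procedure this pipeline reimplements; note that the 95% reported with the
results is the credible interval of the overlap posterior, while α is the
niche-region level, a separate knob that the original description leaves
implicit. Overlap is asymmetric by construction (a tight group nested in a
wide one overlaps it strongly, not conversely) and invariant under common
affine transformations of all groups. Groups with n ≤ d are rejected by
name: the posterior scale matrix would be singular.

## The synthetic-data generator

No raw measurements were deposited for the original specimens — only
museum IDs — so `generate_dataset()` emulates the *statistical structure*
of the study at its published design points: group sizes 14/10/19/13/14;
bite-force offsets ordered allopatric red > hybrid-zone red > hybrids >
allopatric Douglas > hybrid-zone Douglas (red squirrels bite harder,
hybrid-zone populations are weaker than allopatric conspecifics, hybrids
sit nearest hybrid-zone red squirrels); greater premaxillofrontal,
maxillofrontal and sagittal complexity on the red side with flat
nasofrontal and coronal sutures; Douglas squirrels smaller, hybrid-zone
Douglas enlarged; hybrid Q from a Beta(2, 2) restricted to (0.10, 0.90).
All offsets are strictly ordered — the hybrid / hybrid-zone-red gap is the
smallest (0.02 log10 N) — because an exact tie would make rank-recovery
checks undefined.

Mechanics: incisor dimensions are solved backwards from a target
log10 bite force (reference allometric baseline + group offset + sex
effect + Gaussian noise) at a fixed width-to-length aspect ratio; suture
traces are sinusoids on a chord whose amplitude is root-solved so the
measured polyline LR hits its target within 1e-3 (an LR target below 1 is
a configuration error); mandibles are the deterministic spline-based
template (`fixture_template()`, also shipped as
`inst/extdata/mandible_template.tps`) plus smooth displacement fields,
allometry, and landmark noise, then scaled, rotated and translated at
random so the Procrustes machinery is genuinely exercised. The
displacement fields are projected onto the orthogonal complement of the
similarity group (translation, rotation, scaling) at the template and
orthonormalized — otherwise most of a nominal "effect" would be removed by
superimposition and the configured effect size would be a fiction. Every
dataset is byte-reproducible from its seed, and the ground truth (latent
offsets, true classes, latent sizes) is returned and serialized alongside.

Calibration of the shape conditions: group displacement magnitude 0.02
Procrustes units against per-coordinate landmark noise of 0.003, and
allometry of 0.4 Procrustes units per log10 centroid size with a
within-group size sd of 0.025 log10 units. These were set so the
generated data reproduce the *reported magnitudes* of the original
analyses — a shape ANOVA with a dominant group term (F ≈ 20–30, R² ≈ 0.5)
and a clearly significant allometric term (F ≈ 10), and a bite-force
ANCOVA F of the published order — under bending-energy sliding, whose
noise amplification (above) would otherwise drown a naively small effect.

What the generator does **not** emulate: real landmark covariance
structure (noise is isotropic), group-specific allometry (the group:size
interaction is null by construction), measurement-error correlation
between trait systems, asymmetric damage/missingness patterns, and any
actual squirrel anatomy beyond a topologically plausible mandible outline.
Passing tests on generated data therefore validate the *machinery* —
estimators, permutation schemes, posterior sampling, bookkeeping — not
biological conclusions about real specimens.

## Pipeline orchestration

`run_squirrel_analysis()` chains the stages (bite force → sutures → shape
→ overlap → admixture regressions) with a mandatory master seed expanded
into independent per-stage seeds, so toggling one stage off never shifts
another stage's results. Any stage failure aborts with the stage named.
`write_report()` emits every tabular result as CSV plus a `manifest.json`
listing each file with the parameters and seeds that produced it. The
package is driven from R; the exported functions and this vignette are the
user interface, and thin shell wrappers are deliberately out of scope.

## Problem sizes in the test suite

The shipped tests run the statistical checks at sizes chosen to give each
assertion adequate power while keeping the default suite under a couple of
minutes: 999-permutation defaults are exercised at 99–199 permutations
where only calibration (not resolution) matters, the overlap
identical-group check runs at the full 3000 × 10,000 draws, the null
calibration of permutation p-values uses 200 replicates, the axis-test
calibration 50 replicates of 200 × 10 data, and the end-to-end recovery
sweep 20 generator seeds. The acceptance script runs the entire pipeline
at the study's full settings.

## Known limitations

* 2-D landmarks only; no surface patches and no
  minimum-Procrustes-distance sliding (bending energy is the only
  criterion, as specified).
* Univariate models are homoskedastic (no Welch corrections).
* The Monte Carlo overlap estimate has sampling error of order
  `sqrt(p(1-p)/n_mc)` per draw; extremely small overlaps are reported as
  0 rather than resolved.
* Sequential (Type I) sums of squares make term order meaningful; the
  printed order is part of the design, and reordering changes the
  decomposition.
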