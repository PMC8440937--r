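---
title: "Generating virtual thoracic-aorta cohorts: models, criteria and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generating virtual thoracic-aorta cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aortacohort)
```

## The problem

In-silico trials need cohorts of anatomies, but clinical meshes are scarce:
segmenting a thoracic aorta from CT is semi-manual work, and rare phenotypes
are rare in any hospital archive. The alternative is *virtual cohort
generation*: learn a statistical shape model from a small reference sample,
draw new shape codes from it, and keep only the candidates that a clinical
*acceptance function* approves. Two quantities matter: the **efficiency**
`e = |{a in C1 : A(a) = 1}| / K1` — the fraction of generated anatomies that
pass — and the statistical fidelity of the accepted cohort to the reference
population.

This package implements that pipeline end to end for arch-shaped tubular
anatomies: a procedural generator of synthetic aortas with known ground
truth, the tube parameterization and its PCA shape space, the 11 anatomical
biomarkers, the data-driven and phenotype (clinically-driven) acceptance
criteria, four feature-space samplers, SVM surrogates that prefilter
candidates before the authoritative criterion, and an experiment workbench
that ties the pieces together.

## Geometry representation

An anatomy is represented by a **centerline** — a clamped cubic B-spline
`alpha(s)`, `s` in `[0, 1]` normalized arc length, valve end at `s = 0` —
and a **wall model** `rho(s, theta)` giving the wall distance from the
centerline in the local frame. Any wall point is reconstructed by the tube
equation

```
x(s, theta) = alpha(s) + rho(s, theta) (cos(theta) v1(s) + sin(theta) v2(s)).
```

The normal directions `v1, v2` are **rotation-minimizing frames** propagated
from `s = 0` by the double-reflection method. Frenet frames were rejected:
they flip wherever the curvature crosses zero, which happens twice on every
arch-shaped centerline. Frames are propagated on a fixed grid of 1025
stations with one final double-reflection step to the query parameter, so a
frame at a given `s` is the same number no matter what else is evaluated.

The wall model is a least-squares tensor-product fit. In the **theta**
direction the default basis is the periodic trigonometric set
`{1, cos, sin, cos 2t, sin 2t, cos 3t, sin 3t}`; a plain bivariate cubic
polynomial is *not* periodic in `theta`, and the literal cubic basis is kept
behind `mode = "literal"` (its seam gap `rho(s, 0) - rho(s, 2*pi)` is
reported). In the **s** direction the basis is a clamped cubic B-spline with
`n_s = 24` coefficients rather than a single cubic: the sinuses of Valsalva
are a bulge of roughly 0.1 units of arc length, far below what one cubic
across the whole vessel can resolve, and the round-trip accuracy targets
below are unreachable without resolving it. A light second-difference
penalty stabilizes thinly covered knot spans near the tube ends; the higher
theta harmonics, which carry the least data, are penalized more, while the
mean-radius term that carries the bulge is penalized least. The penalty
vanishes for any radius field linear in `s`, so constant-radius recovery is
exact.

### Centerline extraction

Meshes arrive as triangle soups, so the centerline must be estimated. The
extractor orders vertices by the two-ended geodesic fraction
`d1 / (d1 + d2)` (graph distances from the two ends), which keeps the
initial bands roughly perpendicular to the vessel even where the inner and
outer curves of the arch have different path lengths. It then refines:
vertices are projected onto a provisional spline, and at each station the
section center is estimated by an **algebraic circle fit** (Kasa) of the
in-plane coordinates. A fitted circle center, unlike a centroid, is
insensitive to uneven angular coverage, which is what otherwise biases the
estimate wherever bands catch partial vertex rings. Radius outliers per
section (end-cap fans, any cross-limb leakage) are rejected against the
local median before fitting. The spline fit uses soft natural end
conditions (`alpha''` pushed to zero at the ends), which suppresses the end
flare a plain least-squares spline develops and is correct for vessels
trimmed with straight inlet/outlet segments.

With 10 control points (the default) the extracted centerline of a
noise-free synthetic arch lies within a millimeter of the truth, and the
parameterize-reconstruct round trip is below 1% of the mean radius.

## The shape space and feature vectors

Flattened parameterizations (centerline control points plus wall
coefficients, a fixed documented order) are decomposed by centered PCA.
Modes are orthonormal right singular directions with variances
`d^2 / (K - 1)`; each mode's sign is fixed by making its largest loading
positive so the space is reproducible. Coefficients enter PCA unscaled —
both blocks are in millimeter-derived units — with a standardization flag
deliberately left out of the default path.

`choose_dim()` implements the 95% explained-variance rule. On synthetic
cohorts the raw variance is dominated by the large centerline coefficients,
so the 95% rule can return very few modes and truncate exactly the wall
detail (the aortic-root radii) that the phenotype rules read. The
experiment drivers therefore default to **16 modes**, the dimensionality of
the reference study design, with the variance rule available through
`n_modes = NULL`.

## Biomarkers

Eleven scalars describe an anatomy: radii at five landmarks — sinuses of
Valsalva (SoV), sinotubular junction (PA), mid-ascending (MA), arch top
(PT), descending point opposite PA (PD) — the centerline length from the
valve to PD (LPD), the mean analytic curvature of the centerline from PA to
PD (k, in 1/mm), arch height `h`, arch width `w`, `h/w`, and tortuosity
`tor = 1 - w / LPD`. Every radius is the semi-major axis of the best-fit
ellipse of the cross-section (direct least-squares conic fit with the
ellipse constraint; second-moment fallback for degenerate sections).

Landmark placement is a convention, not an inference: PT is the interior
maximum of centerline height, PD is found by bisection at the height of PA
past the arch, SoV is the maximum of the mean wall radius over the aortic
root with a fixed fallback at `s = 0.04` when no bulge is detected, and PA
and MA default to `s = 0.10` and `s = 0.20`. All five are arguments.

Numerical choices: arc length uses adaptive quadrature (relative tolerance
1e-8); mean curvature uses composite Simpson on a fine fixed grid because
`|alpha' x alpha''|` has kinks wherever a fitted spline's curvature touches
zero, which defeats adaptive rules. Mean curvature of a least-squares
spline is *upward-biased* relative to the generating curve: fitting ripple
enters `|kappa|` without sign cancellation. On noise-free synthetic arches
the bias is about +5 to +10% at the default resolution, while radii, LPD
and tortuosity track the generator within 2% and `h`, `w` within 3% (the
extra percent being the station-alignment convention between the fitted and
true arc-length scales). The ground-truth consistency test asserts exactly
these bounds, and no acceptance decision depends on comparing `k` against
an external value — the published scale of `k` is itself ambiguous, and the
criteria only ever compare `k` against statistics computed by the same
pipeline.

## Acceptance criteria

Three data-driven interval criteria are fitted per biomarker on a reference
table (all intervals closed, so a range criterion accepts its own training
data exactly):

* **range**: the observed `[min, max]`;
* **two-sigma**: `mu +/- 2 sigma`, an outlier rejection under approximate
  normality;
* **unimodal Chebyshev**: `M +/- 3B` with `B = sqrt(sigma^2 + (mu - M)^2)`,
  which for any unimodal distribution covers at least 95% of the mass. `M`
  is the half-sample mode — deterministic, robust, no bandwidth choice; a
  KDE-argmax alternative was rejected for its bandwidth dependence.

Because `B >= sigma` and `|mu - M| <= B`, the two-sigma interval is always
nested inside the Chebyshev interval, so two-sigma acceptance implies
Chebyshev acceptance — a property asserted over random statistics in the
tests and visible as a column ordering in every report.

The **phenotype rule** classifies the aortic root from the SoV, PA and MA
radii: N (`SoV > PA` and `SoV >= MA`), A (`SoV > PA` and `SoV < MA`),
E (`SoV <= PA`). The three rules partition the space of radius triples.
Criteria compose by intersection (logical AND), whose efficiency can never
exceed any factor's.

## Samplers

All samplers are pure functions of (inputs, seed):

* **bootstrap** — each coordinate drawn independently from the observed
  values of that coordinate. This is the literal construction; it preserves
  marginals and destroys inter-mode correlation. A whole-vector variant is
  available via `joint = TRUE` for comparison.
* **Gaussian** — sample mean and covariance (denominator `K0 - 1`), sampled
  through a symmetric eigen factorization with negative eigenvalues clipped
  at zero and flagged.
* **uniform** — independent uniforms on the per-coordinate observed
  `[min, max]` box.
* **GAN** — a small tabular generative adversarial network: latent
  dimension 16, generator and discriminator each two hidden layers of 32
  leaky-ReLU units, Adam at 1e-3, minimax training with binary
  cross-entropy, batch 5, 2000 epochs by default (the schedule under which
  the discriminator accuracy stabilizes on cohorts of this size; the
  per-epoch log is kept on the model for inspection). Feature vectors are
  standardized per coordinate before training and de-standardized on
  sampling. The forward/backward passes are implemented directly in base R;
  at 16 dimensions there is nothing a deep-learning runtime would add but
  weight.

## Surrogate screening

When evaluating the acceptance function is expensive (in general it can
involve simulation), a fast classifier can prefilter candidates. Two
surrogates are provided: a radial-basis SVM predicting the two-sigma
criterion's verdict, and a linear-kernel one-vs-one SVM predicting the
phenotype, both with stratified k-fold cross-validated accuracy (folds are
seeded). In the two-stage pipeline only surrogate-accepted candidates reach
the true criterion, so the efficiency of the expensive stage is
`TP / (TP + FP)` of the surrogate — among candidates passed on, the
fraction truly accepted. The false-negative rate is reported alongside,
because anatomies wrongly rejected by the surrogate never reach the cohort
and bias it; the true criterion remains authoritative, so the final cohort
contains no false positives by construction. Random-forest mean decrease in
impurity ranks the feature-space modes by how much they drive the decision,
and `accuracy_vs_topn()` retrains on the top-n modes to show how many are
needed.

## The synthetic population

The generator emulates the anatomy class of an elderly clinical cohort with
ascending dilation: a planar arch (straight ascending limb, semicircular
arch, straight descending limb) with **curvature-continuous** smoothstep
transitions at the junctions — real vessels have no curvature jumps, and a
C2 truth is representable by the cubic-spline fits used downstream; the
transitions are symmetric, so the total turning remains exactly pi and the
true mean curvature between stations bracketing the arch stays in closed
form. The wall is a natural-spline baseline through the valve,
sinotubular, mid-ascending, arch-top and descending radii, plus a
compact-support cosine-squared sinus bulge and a `cos(2*theta)` ovality
modulation (which makes the semi-major-axis measurement non-trivial; note
such a section is elliptical to first order in the ovality only).

Default population parameters were chosen once to land the biomarker means
and spreads in the regime of the published 26-patient statistics (arch
width near 70 mm, valve-to-PD length near 235 mm, root radii 12-18 mm,
tortuosity near 0.70) with phenotype mixture `N:A:E = 0.115:0.535:0.35`.
Mixtures are realized by rejection: a label is drawn from the mixture and
shape parameters are redrawn until the ground-truth rule produces it, so
labels are exact in expectation while parameters keep their conditional
distributions. The ground-truth sinus peak is taken over the aortic root
only (`s < 0.10`), since the rise toward a dilated mid-ascending segment is
not sinus anatomy.

What the generator does **not** emulate: branch vessels, non-planar arches,
segmentation artifacts beyond isotropic radial noise, wall thickness, or
any hemodynamics. Tests passing on this population show that the pipeline
measures what the generator encodes; they do not certify accuracy on
clinical segmentations.

## Experiment workbench and problem sizes

`run_data_driven()` reproduces the first experiment family: reference
cohort, PCA space, the four samplers, the three data-driven criteria and a
per-biomarker two-sided rank-sum (Mann-Whitney-Wilcoxon) fidelity test at
alpha 0.05 without multiplicity correction (a Bonferroni flag exists),
reported as "x / 11 reject H0". `run_clinically_driven()` splits a
bootstrap base cohort by phenotype into per-phenotype references and
reports, per sampler and target phenotype, the data-driven columns
(anchored on the original reference sample), the three phenotype fractions
— a confusion-style block whose diagonal is the clinically-driven
efficiency — and the three intersections. `run_two_stage()` trains the
binary surrogate on a Gaussian-sampled cohort labeled by the true
criterion (whose statistics are estimated on the bootstrap base cohort)
and evaluates on a held-out uniform cohort.

Candidate vectors whose decoded geometry is invalid (non-positive wall
radius, no interior height maximum) are counted as rejected and reported
separately; the reference design is silent on geometric invalidity, and
silently dropping them would inflate efficiency.

Full-scale defaults mirror the reference design (26 reference anatomies,
data-driven cohorts of 3000, 1000 per phenotype, bootstrap base 3000,
surrogate training 15000). The package's own test and acceptance runs use
the scaled sizes `K1 = 300` (data-driven) and `K1 = 100` per phenotype with
a bootstrap base of 300 — the sizes at which the complete report matrices
and every monotone bound are exercised while a full run stays in the
minutes range on one core. All randomness derives from a single
configuration seed through fixed child-seed offsets.

## Known limitations

* Mean curvature carries the spline-ringing bias discussed above; compare
  `k` only against values produced by the same measurement convention.
* The wall model's constant extension beyond `s` in `[0.015, 0.985]` makes
  the last ~1.5% at each end cylindrical; landmarks are all interior to
  this range.
* Coordinate-wise bootstrap destroys mode correlations by construction; a
  per-phenotype reference cohort that was itself bootstrap-generated keeps
  shrinking the set of attainable coordinate values, which is visible as
  phenotype leakage in the clinically-driven reports.
* The GAN is a small fully-connected network adequate for 16-dimensional
  mode coefficients; it is not a mesh generator and has no notion of
  geometric validity.
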