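---
title: "Assessing pelvic lymph node treatment response from segmentation masks"
author: "metradsp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing pelvic lymph node treatment response from segmentation masks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metradsp)
```

## The problem

In advanced prostate cancer, pelvic lymph nodes are a principal metastatic
site, and treatment response is monitored on serial MRI — typically axial
diffusion-weighted imaging (DWI) — by measuring each node's **short-axis
diameter** and applying MET-RADS-P nodal criteria, which follow the RECIST 1.1
logic for nodes. Doing this by hand is slow and operator-dependent. When an
upstream segmentation source (a deep-learning model, a trained reader, or a
phantom generator) can produce 3D node masks, everything downstream of the
mask is mechanical: measure diameters, classify node size, track nodes over
time, and apply the response rules. `metradsp` implements that mechanical
part, segmentation-agnostically, together with the statistical battery used
to compare two sources of masks or assessments.

The pipeline is deliberately *semiautomated*: node correspondence across
timepoints is solved automatically by centroid proximity, but a manual
correspondence table always takes precedence, reflecting how a radiologist
supervises such a system in practice.

## Measurement model

### From mask to objects

A `label_volume` is a 3D array of non-negative integer labels plus voxel
spacing in mm. Objects are extracted either by trusting the instance labels
(`relabel = FALSE`) or by 26-connectivity connected components over the
foreground (`relabel = TRUE`). The default connectivity is 26 because nodes
are compact blobs and 4 mm slice gaps easily split a 6-connected component;
6-connectivity remains available. Objects below 2 voxels are discarded by
default: a single voxel has no measurable in-plane geometry and is almost
always segmentation noise. No resampling is ever performed — all measurements
use the native anisotropic spacing, because that is the grid on which masks
are drawn and checked.

### Diameters

On every axial slice a node occupies, each foreground pixel contributes its
four physical corner points. The **long axis** is the Feret diameter of this
corner set — the maximum pairwise distance between convex hull vertices,
which equals the brute-force maximum over all corners exactly. The **short
axis** is the extent of the hull perpendicular to the long axis, the RECIST
reading of "short axis". Corners (rather than pixel centres) match
caliper-style manual measurement and remove the half-pixel underestimate;
the cost is a positive bias bounded by one pixel diagonal
(`sqrt(s1^2 + s2^2)`).

One numerical subtlety: on a rasterized thin section, many corner pairs are
within rasterization noise of the true long axis, and the pair that happens
to win can be tilted by a few degrees, inflating the perpendicular width
(for a section with semi-axes 15 and 2.5 mm at 1 mm pixels, by ~0.2 mm plus
jagged-boundary noise, which in ~2.5 % of random thin sections pushed the
total short-axis error past one pixel diagonal). The short-axis direction is
therefore chosen among *all* corner pairs whose separation is within one
pixel diagonal of the Feret diameter, taking the smallest perpendicular
extent; exact ties fall back to lexicographic vertex order, so the result is
deterministic. Across 600 random rasterized ellipses (axes 4–30 mm, all
rotations, isotropic and anisotropic pixels) the maximum axis error after
this change is 0.99 pixel diagonals. The long-axis *value* is unaffected —
it is still the exact Feret diameter.

The lesion-level measurement is taken on one slice, selected by
`slice_rule`:

* `"area"` (default): the slice with the largest in-plane area, ties going
  to the lowest slice index — where a radiologist would measure;
* `"short"`: the slice maximising the short axis.

A single-pixel section returns `(max(spacing), min(spacing), pixel area)` by
convention. Degenerate inputs (empty sections, empty volumes) return empty
results rather than errors wherever a loop over nodes could encounter them.

## Response model

### Size categories

With short-axis diameter $d$ (mm), a node is **nonpathological** when
$d < 10$, **nontarget** when $10 \le d < 15$, and a **target** lesion when
$d \ge 15$. Bounds are closed from below (exactly 10.0 is nontarget, exactly
15.0 is target). Both thresholds live in `response_rules()` and can be
changed in one place.

### Longitudinal matching

Baseline and follow-up nodes are paired greedily by ascending physical
centroid distance, accepting pairs closer than 15 mm (configurable). Greedy
matching agrees with exhaustive optimal assignment whenever nodes are
separated by more than twice the perturbation of their centroids, which
holds for anatomically plausible node spacing; the tests verify this against
a brute-force assignment oracle. Manual links are taken verbatim first and
validated for one-to-one-ness. Follow-up nodes left unmatched are *new*;
baseline nodes left unmatched are *disappeared* and contribute 0 mm to all
sums, the standard handling of lesions too small to see.

### Rules

Let $S_t$ be the sum of short diameters of the baseline-designated target
nodes at timepoint $t$, and the nadir the minimum of $S$ over baseline and
all earlier follow-ups. For **target** disease:

* **CR** — every target node $< 10$ mm (takes precedence over PD, so a
  reappearing 6 mm remnant after complete disappearance is still CR);
* **PD** — $S_t - \mathrm{nadir} \ge 20\%$ of the nadir *and* $\ge 5$ mm;
* **PR** — $S_t \le 70\%$ of baseline;
* **SD** — otherwise.

All comparisons are inclusive. Target designation is fixed at baseline and
carried forward; a target that shrinks below 15 mm stays in the sum. An
optional cap on the number of targets (largest first) exists and is off by
default, since the source criteria cap target counts but a
segmentation-driven pipeline has no reason to discard measured lesions.

**Nontarget** disease is followed qualitatively: CR when every baseline
nontarget node drops below 10 mm and no new pathological node has appeared;
PD on any new pathological node (an unmatched follow-up node $\ge 10$ mm) or
on *unequivocal progression*. The criteria do not quantify "unequivocal";
it is operationalized here as a baseline nontarget node reaching target size
($\ge 15$ mm) with both $\ge 20\%$ and $\ge 5$ mm growth, and the rule
version string is echoed into every report so downstream users can see which
operationalization produced a call. **Nonpathological** nodes can only
progress (any of them reaching 10 mm) or stay stable; CR/PR do not apply, so
this category uses the {SD, PD} alphabet.

Every call is stored next to its evidence (baseline sum, current sum, nadir,
percent and absolute changes, new-node count), and the non-CR calls are
reproducible from the evidence columns alone.

## Agreement battery

* **DSC** $= 2|A\cap B|/(|A|+|B|)$ and **VS** $= 1 - ||A|-|B||/(|A|+|B|)$,
  per whole foreground or per node (both modes exist because published
  segmentation studies are often ambiguous about which they used). Per-node
  pairing is by maximal voxel overlap, greedy; unpaired nodes score 0 so
  misses and false positives penalise subgroup means. Two empty masks are
  defined as agreeing (DSC = VS = 1) with a `degenerate` flag. DSC ≤ VS is
  an identity, asserted over random masks in the tests.
* **Bland–Altman** on percent differences, $100(a-b)/\frac{a+b}{2}$, which
  is robust to the size composition of the sample; limits of agreement are
  mean ± 1.96 sample SD, and the fraction of pairs inside the LOA is
  reported.
* **Cohen's kappa** (unweighted) over the fixed alphabet CR, PR, SD, PD,
  with the Fleiss–Cohen–Everitt asymptotic SE for the 95 % CI (the source
  criteria do not prescribe a CI method; this one is named in the report
  header). Accuracy uses a Clopper–Pearson exact CI via `binom.test`. When
  both raters use a single category throughout, chance agreement is 1 and
  kappa is undefined; it is reported as 1 under perfect observed agreement,
  NA otherwise, with a `degenerate` flag.

## The phantom generator

`phantom_spec()` / `rasterize_phantom()` build label volumes of rotated
ellipsoids on a DWI-like grid — defaults 256 × 256 × 24 voxels at
1.75 × 1.75 × 4 mm, i.e. the in-plane resolution and 4 mm slice thickness
of a typical axial pelvic DWI acquisition, small enough for seconds-scale
tests. Rasterization is by centre-of-voxel inclusion, so the ground truth
is unambiguous; tolerance budgets in the tests absorb the sub-voxel effects
instead of modelling partial volume.

`simulate_series()` scales, removes, or adds nodes per follow-up and emits
the *intended* per-category calls computed by plain threshold arithmetic on
the intended diameters — deliberately duplicated, minimal code, independent
of the rules engine, so end-to-end tests compare two implementations that
share only the threshold constants.

`simulate_cohort()` draws per-patient node sets (1–2 targets at 26 or
30 mm, 1–2 nontargets at 12.5 mm — the centre of the nontarget band, the
only point at least one pixel diagonal from both the 10 and 15 mm cuts —
and 1–2 nonpathological nodes at 6 mm; realistic counts for a pelvic nodal
station survey) and trajectories from size-factor sets chosen once so that
every intended diameter and sum change clears the 10 mm, 15 mm, 20 %, 30 %
and 5 mm decision boundaries by at least the corner-hull measurement-error
budget of ~one in-plane pixel diagonal (~2.5 mm) per node: targets 0
(vanish → CR), 0.5 (−50 % → PR), 1.0 (SD), 1.5 (+50 % → PD); nontargets
0.55, 1.0, 1.9; nonpathological 1.0 and 2.2; plus occasional new 12.5 mm
nodes. Percent-change rules are the binding constraint — a ratio of two
measured sums sees the error of both ends, so the PR factor sits at 0.5,
whose worst observed measured ratio (0.614 over 300 probe draws per size)
stays clearly below the 0.7 boundary. Through-plane semi-axes of
pathological nodes are at least 2.4 slice thicknesses, capping equatorial
slice-sampling loss below ~0.3 mm. Inside these budgets, measured
categories and calls equal intended ones, which is what the 20-patient
end-to-end test and the acceptance script check (100 % agreement, κ = 1).

`perturb_mask()` emulates automated-vs-manual disagreement by eroding or
dilating each node by `round(rnorm(1, 0, sd))` one-voxel morphological
steps. Because the standard-normal draws are fixed by the seed and only
scaled by `sd`, perturbation strength is *coupled* across levels (common
random numbers): each node's boundary shift is monotone in `sd`, so mean
DSC is monotonically non-increasing across levels by construction, not just
in expectation — the property the degradation test asserts.

What the phantoms do **not** emulate: irregular node shapes, contact
between adjacent nodes, partial-volume boundaries, intensity information,
registration error between scans, or reader variability in *finding* nodes.
Passing the synthetic tests therefore validates the measurement and rules
machinery, not segmentation quality on real DWI.

## Numerical and design choices

* Thresholds are compared inclusively with plain floating-point `>=`; the
  engine and its oracles compute percent criteria with identical
  expressions, so boundary cells agree bit-for-bit.
* Greedy matching and greedy overlap-pairing tie-break deterministically
  (ascending distance / descending overlap, first hit wins in scan order);
  re-running any step with the same inputs and seed is byte-identical,
  which the report tests assert via `readLines` equality.
* Connected-component labelling is a vectorized frontier flood fill written
  in R; node ids after relabelling are assigned by descending volume with
  lexicographic first-voxel tie-break, so labels are stable under
  permutation of input label values.
* The problem sizes in the tests (100 phantom sections, 20-patient cohort,
  1000 random mask pairs, 10 000 simulated call pairs) were chosen as the
  smallest sizes at which each property is sharply distinguishable from
  chance; they run in about a minute in total.

## Known limitations

* Diameters are in-plane only; a node whose true short axis is oblique to
  the axial plane is measured as its axial projection, as in clinical
  practice, but no 3D principal-axis alternative is offered.
* Matching is centroid-based; grossly deforming anatomy between scans can
  defeat it, which is exactly the case the manual-links override exists for.
* The whole-body MET-RADS-P apparatus (bone/visceral/primary patterns,
  regional response categories) is out of scope; only the nodal CR/PR/SD/PD
  logic is implemented.
* Kappa CIs are asymptotic and accuracy CIs exact; with very few pairs per
  category the kappa CI is unreliable (the accuracy CI is not).
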