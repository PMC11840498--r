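---
title: "Methods: auditing auto-segmentation editing with the surface Dice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: auditing auto-segmentation editing with the surface Dice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Deep-learning auto-segmentation (DLAS) now delineates most organs at risk
(OARs) for radiotherapy planning, and every DLAS contour is supposed to be
reviewed and, where necessary, edited before clinical approval. Once a tool
is in routine use, nobody has time to re-review thousands of structures by
hand — yet the risks of routine use (automation bias, silent vendor model
updates, drifting local practice, occasional gross failures) are exactly the
things that only show up *after* the evaluation phase. `oaraudit` implements
a script-style audit of that editing: for every structure it compares the
raw DLAS mask with the final approved mask, reduces the comparison to two
numbers — a surface agreement score and a used-unedited flag — and
aggregates them per OAR and per calendar period so that trends and outlier
cases stand out.

## The metric

For masks $A$ and $B$ on a shared voxel grid, let $S_A$, $S_B$ be their
surfaces and $\tau$ a physical distance tolerance. The surface Dice
similarity coefficient is

$$
\mathrm{sDSC}_\tau(A,B) \;=\;
\frac{\bigl|\{\,s \in S_A : d(s, S_B) \le \tau\,\}\bigr| +
      \bigl|\{\,s \in S_B : d(s, S_A) \le \tau\,\}\bigr|}
     {|S_A| + |S_B|},
$$

the fraction of the combined surface lying within $\tau$ of the other
surface. Unlike the volumetric Dice $2|A\cap B|/(|A|+|B|)$, it scores the
*amount of boundary a human would have to redraw*, which is why it tracks
editing effort much better than volume overlap; a 1 mm systematic shift of a
large organ barely moves volumetric Dice but is either entirely inside or
entirely outside the tolerance. The default tolerance is 3 mm — the
conventional choice for this audit — with a per-OAR override in the
protocol configuration, since one tolerance does not suit every organ.

Implementation choices, each of which is a genuine decision rather than a
forced move:

* **Surface elements are border-voxel centres with unit weight.** A border
  voxel is a foreground voxel with a face-adjacent (6-connected) background
  neighbour; out-of-grid counts as background. The best-known reference
  implementation of the surface Dice weights surface elements by the area
  of a marching-cubes face instead. We use unit weights because the
  resulting statistic has an *exact* brute-force oracle (enumerate both
  surfaces, compare all pairwise distances), which lets the test suite pin
  the implementation to $10^{-9}$; the weighting is isolated behind
  `extract_surface()`, so an area-weighted variant would be a local change.
  For audit purposes the two weightings move together; absolute values can
  differ by a few percent on coarse grids.
* **Distances are exact Euclidean distances in physical mm.** A separable
  squared distance transform (lower-envelope-of-parabolas) runs over the
  grid with per-axis spacing, seeded on the opposite surface's voxel
  centres. Because the seeds are the surface voxels themselves — not the
  mask complement — the transform is exact everywhere *including at the
  grid edge*, so no padding is applied; structures touching the grid
  boundary are handled correctly by construction, which the oracle tests
  confirm on edge-touching masks. Comparisons are made on squared
  distances, whose arithmetic is exact for the integer voxel offsets and
  exactly representable spacings used in practice, so points at exactly
  $\tau$ classify consistently.
* **Empty-mask conventions.** Both surfaces empty → sDSC 1 (an absent
  structure left absent is "no edit"); exactly one empty → 0 (wholesale
  addition or deletion is maximal editing).
* **Unedited = voxel-exact identity** of the foreground sets, nothing
  looser. The identity implies sDSC 1 at any tolerance; `evaluate_pair()`
  short-circuits accordingly.

## The audit pipeline

A cohort manifest (CSV or JSON) lists patient id, ISO-8601 date, recorded
structure name, and the two mask paths. Names are matched to the protocol
after case-folding and stripping whitespace/underscores, directly or
through configured aliases; rows that fail name matching, date parsing,
file loading, or the shared-grid requirement are recorded as unresolved
with a reason and reported as a failure rate — never silently dropped and
never "fixed" by resampling. This mirrors how script audits actually
behave against clinical systems: structures named off-protocol are missed,
and the miss rate is itself a quantity worth monitoring.

Dates are binned into consecutive blocks of `period_length_months` calendar
months from `audit_start` (boundary dates belong to the later block); an
18-month audit at 2-month periods spans indices 0–8. Per (OAR, period) cell
we report n, % unedited, and mean/SD/min/max sDSC, with the *population* SD
(divisor $n$): the cell is a census of the period's cases, not a sample
from a larger one, and single-case cells then report SD 0 rather than NA.
Empty cells are absent, not zero-filled.

Cross-OAR summaries average the per-OAR means *unweighted* (with min–max
ranges over OARs), so frequent organs do not dominate the trend; pooling
over ROIs instead is available via `weight = "roi"`. Which of the two a
given published audit used is usually ambiguous; we default to OAR-level
aggregation and expose both. An exclusion list removes OARs whose practice
changed mid-audit from the trend without touching the per-OAR tables.

Outliers are flagged one-sidedly: within each OAR (pooled over periods,
requiring at least `min_n_for_outlier = 5` cases), any case with
$\mathrm{sDSC} < \bar{x} - k\,s$ is flagged, default $k = 2$. Low sDSC
(heavy editing) is the anomaly worth investigating; unusually *light*
editing is not flagged, because it is indistinguishable from a good
contour. With zero spread no case is flagged. The choice of a numeric
mean-minus-$k$-SD rule (rather than visual inspection) and of $k=2$ is
ours; $k$ is a config knob.

## The synthetic cohort generator

No clinical masks ship with the package, so every pipeline stage is
exercised against generated cohorts whose ground truth is known. The
generator emulates the *editing process*, not anatomy: an ellipsoid stands
in for compact parallel organs (bladder-like), a z-axis tube for serial
organs (spinal cord, oesophagus), rasterized at voxel centres on a 48³ grid
at 1 × 1 × 2.5 mm by default. Each patient's DLAS mask gets anatomical
jitter (±5 % radii, ±2 mm centre) so unedited detection is tested against
genuinely distinct patients. The final mask is a bit-identical copy with
probability `p_unedited`, otherwise one draw from an edit mixture:

* `edit_margin(m)` — exact Euclidean dilation/erosion by `m` mm (the
  distance-transform threshold), e.g. a cord grown by 1 mm;
* `edit_crop(f, side)` — removal of a fraction `f` of the occupied
  z-slices from the superior or inferior end (side randomized per case by
  default), the serial-organ longitudinal edit and the
  "only part of the organ was contoured" failure mode;
* `edit_bump(count, r, d)` — local spherical patches of radius `r`
  protruding or indenting by `|d|` mm, small local corrections.

Randomness is counter-based: each case's RNG substream seed is a
deterministic hash of (master seed, period, patient, OAR), so cohorts are
bit-reproducible and independent of generation order. Dates are drawn
uniformly inside each period's calendar window.

Shipped presets define the study conditions and are not tuning knobs:

* `steady_state` — `p_unedited` 0.40 everywhere, fixed small edits: the
  regime a department reaches once a tool is accepted (about 40 % of
  contours needing no edit).
* `drift` — `p_unedited` rising 0.215 → 0.40 and edit magnitude falling
  2 → 0.5 mm over nine periods. Note an audit at fixed tolerance can only
  *see* a magnitude drift if some edits cross the tolerance: a 1 mm margin
  is invisible at 3 mm. Early-period patch depths (up to 4 mm) and crops
  (0.3 of the z-extent) therefore exceed the tolerance, late ones do not —
  the same asymmetry a real 3 mm audit exhibits. A related voxel effect:
  a 0.5 mm margin is below the 1 mm in-plane voxel size, changes no voxel,
  and is counted as *unedited* by the identity test, so the audited
  unedited fraction in late periods exceeds the generating `p_unedited` —
  exactly as a voxel-level audit of sub-resolution edits would.
* `model_update` — an extra OAR needing a superior-extent correction in
  nearly every case until a configured period, then almost none: the step
  signature of a vendor model fix.
* `partial_failure` — the oesophagus tube loses its superior 60 % with
  probability 5/11 in one period only.
* `parameter_recovery` — one OAR, one period, `p_unedited` 0.6, 200
  patients: the statistical check that the audited unedited percentage is a
  consistent estimator of the generating probability.

What the generator does **not** emulate: real organ shapes and neighbours,
CT content and artefacts, deformable or anatomically-informed edits,
inter-observer style. Passing tests therefore demonstrate the *pipeline* —
metric correctness, aggregation, calendar logic, failure accounting,
outlier logic, determinism — not clinical performance of any DLAS model.

## Numerical and testing choices

Problem sizes were chosen to keep the full suite fast while staying in the
regime the audit targets: oracle equivalence on 200 random mask pairs at
grids up to 20³ (where the all-pairs oracle is exact and cheap), parameter
recovery on 50 seeds of 200 patients at 48³, trend recovery on 40 seeds of
nine 20-patient periods at 32³. The recovery checks are statistical by
nature; their acceptance bands (99 % central binomial interval with ≥ 94 %
coverage; positive slope in ≥ 95 % of seeds) were fixed alongside the
scenario definitions.

Degenerate inputs are all defined rather than erroneous: empty masks (see
conventions above), single-voxel structures (their lone voxel is the whole
surface), masks filling the grid (faces are surface), edits that empty a
mask (allowed — emulates deletion), n = 1 cells (SD 0), OARs below the
outlier minimum (skipped and listed). Grid mismatches between a pair are a
recorded failure, never resampled: the clinical workflow compares contours
on the same planning CT, so a mismatch means the manifest is wrong.

## Limitations

* Unit-weighted voxel surfaces differ slightly from area-weighted mesh
  surfaces; absolute sDSC values are comparable only between
  implementations using the same convention.
* DICOM-RT structure sets are out of scope; masks must arrive as NIfTI
  volumes on a shared grid.
* The trend machinery reports slopes, not significance tests.
* Per-user stratification is not implemented.
* Synthetic cohorts validate machinery, not models: none of the numbers
  they produce are estimates of any clinic's editing behaviour.
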