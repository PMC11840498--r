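# oaraudit

Automated auditing of how deep-learning auto-segmentation (DLAS) contours
of organs at risk (OARs) are edited before clinical approval in
radiotherapy.

Departments that adopt DLAS review and edit every auto-contour, but once
the tool is routine nobody can re-review thousands of structures by hand —
and that is precisely when automation bias, vendor model updates and
drifting local practice go unnoticed. `oaraudit` implements a script-style
audit: for each structure it compares the raw DLAS mask with the final
approved mask, reduces the comparison to a surface agreement score and a
used-unedited flag, aggregates per OAR and per calendar period, and flags
cases edited far outside the usual range.

## The metric

For masks $A, B$ on a shared voxel grid with surfaces $S_A, S_B$ and a
physical tolerance $\tau$ (default 3 mm, per-OAR configurable), the
surface Dice similarity coefficient is

$$\mathrm{sDSC}_\tau = \frac{|\{s \in S_A : d(s,S_B) \le \tau\}| + |\{s \in S_B : d(s,S_A) \le \tau\}|}{|S_A| + |S_B|}$$

— the fraction of the combined contour surface that lies within $\tau$ of
the other contour, i.e. the share of boundary nobody had to redraw.
Distances are exact Euclidean distances in mm on anisotropic grids
(separable distance transform, verified against an all-pairs brute-force
oracle to 1e-9). A contour is *unedited* iff the masks are voxel-exactly
identical. Volumetric Dice is included for comparison.

Because clinical structure sets cannot be redistributed, the package ships
a synthetic cohort generator (ellipsoid and tube phantoms; margin, crop
and local-patch edits; per-period parameter drift; counter-based seeding
for bit-reproducibility) so the entire pipeline is testable end to end.

## Worked example

Generate a drifting-editing cohort (nine 2-month periods, 20 patients per
period, three OARs) and audit it:

```r
library(oaraudit)

scenario <- scenario_preset("drift", seed = 1, n_periods = 9,
                            patients_per_period = 20)
generate_synthetic(scenario, "scratch/cohort")
report <- run_audit("scratch/cohort/manifest.csv",
                    preset_audit_config(scenario), "results/audit")
report$per_oar_alltime
```

```
     oar_name total_rois pct_unedited mean_sdsc sd_sdsc
1     bladder        180         39.4     0.998 0.00389
2  oesophagus        180         46.7     0.981 0.04208
3 spinal_cord        180         42.8     0.975 0.04901
```

Each row is one OAR pooled over the whole audit: how many structures were
evaluated, what percentage were used with zero voxel change, and the
mean/SD of the surface Dice at 3 mm. The cross-OAR per-period trend shows
the editing drift the scenario encodes — mean sDSC rising 0.973 → 0.993
and unedited contours 31.7% → 73.3% from period 0 to period 8 — and
`report$outliers` lists the cases below mean − 2·SD of their OAR (44 in
this cohort, dominated by the early heavy-edit periods).

The same steps are laid out as a narrated workflow in `analysis/`:
`01_generate_cohort.R`, `02_run_audit.R`, `03_trends_outliers.R` (tables
land under `results/`). The statistical model, design choices and
limitations are documented in `vignettes/oar-audit-methods.Rmd`.

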