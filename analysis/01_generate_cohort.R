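#!/usr/bin/env Rscript
# Generates the synthetic audit cohort used throughout the analysis: the
# drift scenario — an 18-month audit in nine 2-month periods, 20 patients
# per period, three OARs (a bladder-like ellipsoid and two serial tube
# organs), where the unedited fraction rises from 21.5% to 40% and edit
# magnitudes shrink from 2 mm to 0.5 mm across periods.
#
# Masks (NIfTI) and the manifest land under scratch/cohort/; everything
# downstream regenerates from there.

library(oaraudit)

seed <- 1L
out_dir <- file.path("scratch", "cohort")
unlink(out_dir, recursive = TRUE)

scenario <- scenario_preset("drift", seed = seed, n_periods = 9,
                            patients_per_period = 20)
manifest <- generate_synthetic(scenario, out_dir)

cat(sprintf("cohort: %d structure pairs over %d periods, seed %d\n",
            nrow(manifest), scenario$n_periods, seed))
cat(sprintf("dates span %s .. %s\n", min(manifest$date), max(manifest$date)))
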