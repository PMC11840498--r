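#!/usr/bin/env Rscript
# Trend analysis over the audit report: per-OAR least-squares slopes of mean
# sDSC against period (positive slope = less editing over time), the
# cross-OAR trend with and without excluding an OAR, and the outlier list.
# Writes results/trends.csv.

library(oaraudit)
library(dplyr)

per_cell <- readr::read_csv(file.path("results", "audit", "summary_by_period.csv"),
                            show_col_types = FALSE)
if (nrow(per_cell) == 0) stop("run analysis/02_run_audit.R first", call. = FALSE)

oars <- unique(per_cell$oar_name)
trends <- bind_rows(lapply(oars, function(o) {
  tr <- trend_series(per_cell, o)
  tibble::tibble(oar_name = o,
                 n_periods = nrow(tr),
                 sdsc_slope_per_period = trend_slope(tr),
                 mean_sdsc_first = tr$mean_sdsc[1],
                 mean_sdsc_last = tr$mean_sdsc[nrow(tr)],
                 pct_unedited_first = tr$pct_unedited[1],
                 pct_unedited_last = tr$pct_unedited[nrow(tr)])
}))
readr::write_csv(trends, file.path("results", "trends.csv"), progress = FALSE)

cat("Per-OAR editing trends (positive slope = editing decreasing):\n")
print(as.data.frame(trends), digits = 3)

overall <- summarize_overall(per_cell)
cat(sprintf("\nCross-OAR slope, all OARs:      %+.4f sDSC/period\n",
            trend_slope(overall)))
for (o in oars) {
  ex <- summarize_overall(per_cell, exclude_oars = o)
  cat(sprintf("Cross-OAR slope, without %-12s %+.4f sDSC/period\n",
              paste0(o, ":"), trend_slope(ex)))
}

outliers <- readr::read_csv(file.path("results", "audit", "outliers.csv"),
                            show_col_types = FALSE)
cat(sprintf("\n%d outlier case(s) beyond mean - 2*SD of their OAR:\n",
            nrow(outliers)))
if (nrow(outliers) > 0) print(as.data.frame(outliers), digits = 3)
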