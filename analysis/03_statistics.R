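#!/usr/bin/env Rscript
# Statistical comparison of the two electrode models from the comparison
# table written by 02_run_simulations.R: paired t-tests on regional median
# current densities, regressions of dose percent differences on electrode
# property percent differences, and regressions of regional dose on brain
# volume ratio (the atrophy analysis).

suppressPackageStartupMessages(library(tdcsflow))

cfg <- read_run_config(file.path("analysis", "run_config.yaml"))
out_dir <- cfg$output_dir
tab <- utils::read.csv(file.path(out_dir, "comparison_table.csv"))
tab <- tab[tab$complete, ]

# Paired t-tests: real vs artificial medians per region.
regions <- c("whole_head", "brain", "gm", "wm",
             "sfg_analog", "mfg_analog", "ifg_analog", "temporal_analog")
ttests <- do.call(rbind, lapply(regions, function(rg) {
  tt <- paired_t_test(tab[[paste0("med_", rg, "_real")]],
                      tab[[paste0("med_", rg, "_artificial")]])
  data.frame(region = rg, delta_J = tt$mean_difference, t = tt$t,
             df = tt$df, p = tt$p)
}))
write_table(ttests, file.path(out_dir, "paired_ttests.csv"))

fits_props <- correlate_electrode_properties(tab)
write_table(fits_props, file.path(out_dir, "electrode_property_regressions.csv"))

fits_atrophy <- correlate_atrophy(tab)
write_table(fits_atrophy, file.path(out_dir, "atrophy_regressions.csv"))

message("paired t-tests (real vs artificial):")
for (i in seq_len(nrow(ttests))) {
  message(sprintf("  %-16s dJ = %+.5f A/m^2, t(%d) = %6.2f, p = %.2g",
                  ttests$region[i], ttests$delta_J[i], ttests$df[i],
                  ttests$t[i], ttests$p[i]))
}
dist_wh <- fits_props[fits_props$predictor == "pd_separation" &
                        fits_props$region == "whole_head", ]
area_wh <- fits_props[fits_props$predictor == "pd_area" &
                        fits_props$region == "whole_head", ]
message(sprintf(
  "separation-distance PD predicts whole-head dose PD: R^2 = %.3f, p = %.2g",
  dist_wh$r_squared, dist_wh$p))
message(sprintf(
  "contact-area PD vs whole-head dose PD: R^2 = %.3f, p = %.2g",
  area_wh$r_squared, area_wh$p))
brain_fits <- fits_atrophy[fits_atrophy$region == "brain", ]
message(sprintf(
  "brain dose rises with brain volume ratio: R^2 = %.3f (artificial) / %.3f (real), both slopes %s",
  brain_fits$r_squared[brain_fits$model == "artificial"],
  brain_fits$r_squared[brain_fits$model == "real"],
  if (all(brain_fits$slope > 0)) "positive" else "NOT all positive"))
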