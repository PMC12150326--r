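#!/usr/bin/env Rscript
# Bound vs unbound chiral-axis dihedral occupancy.
#
# Emulates the trajectory analysis: dihedral time series for the
# tubulin-bound and free states are Metropolis-sampled from two
# torsional profiles (binding narrows the well and shifts it toward
# smaller dihedrals), binned into 5-degree windows at midpoints, and
# compared by circular mean, smallest covering arc, mode shift and
# histogram overlap.

library(atropos)
dir.create("results", showWarnings = FALSE)

# unbound: broad solution-phase well near 100 degrees; bound: stiffer
# well pulled toward 85 degrees by the binding site
unbound_prof <- gen_torsion_profile(100, 12, 9, window = "principal")$profile
bound_prof <- gen_torsion_profile(85, 18, 14, window = "principal")$profile

n <- 20000
unbound <- gen_dihedral_series(unbound_prof, temperature = 310, n = n,
                               state = "unbound", compound = "DM-MTC-like",
                               seed = 401)
bound <- gen_dihedral_series(bound_prof, temperature = 310, n = n,
                             state = "bound", compound = "DM-MTC-like",
                             seed = 402)

cmp <- compare_states(bound, unbound, width = 5)
print(cmp)

# the sampler explores both enantiomeric wells only over barriers; at
# these heights each chain stays in its starting well, as bound poses do
occ <- merge(cmp$hist_bound, cmp$hist_unbound, by = "midpoint",
             suffixes = c("_bound", "_unbound"))
write.csv(occ, "results/dihedral_occupancy.csv", row.names = FALSE)

summary_tab <- data.frame(
  state = c("bound", "unbound"),
  circ_mean_deg = c(cmp$bound$mean, cmp$unbound$mean),
  arc_width_deg = c(cmp$bound$range_width, cmp$unbound$range_width),
  circ_sd_deg = c(cmp$bound$sd, cmp$unbound$sd),
  n = c(cmp$bound$n, cmp$unbound$n))
print(summary_tab, digits = 4)
cat(sprintf("mode shift %.1f deg, histogram overlap %.3f\n",
            cmp$mode_shift, cmp$overlap))
write.csv(summary_tab, "results/occupancy_summary.csv", row.names = FALSE)
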