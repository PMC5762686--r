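#!/usr/bin/env Rscript
# Stage 2: pose-reproduction benchmark and hydrogen-bond occupancy.
#
# Redocking the ensemble's crystal ligands gives each structure a success
# rate: the share of poses within 2 A heavy-atom RMSD of the crystal pose.
# Here each structure receives 90 synthetic redockings whose planted RMSD
# distribution encodes its pose fidelity. A set of hydrogen-bond distance
# trajectories (as from an MD run of a docked complex) is scored for
# occupancy at the 3.5 A heteroatom cutoff.

library(screenval)

structures <- read.csv("results/structures.csv")

pose_tbl <- do.call(rbind, lapply(seq_len(nrow(structures)), function(i) {
  # better-separating structures also reproduce poses more faithfully here
  frac_good <- 0.25 + 0.15 * structures$separation[i]
  rmsds <- vapply(1:90, function(j) {
    planted <- if (j <= round(90 * frac_good)) 0.5 + (j %% 10) * 0.15 else 2.2 + (j %% 8) * 0.4
    heavy_atom_rmsd(gen_pose_pair(24, planted, seed = 1000 * i + j))
  }, numeric(1))
  data.frame(structure_id = structures$structure_id[i],
             pose_success_pct = success_rate(rmsds, threshold = 2.0))
}))
write.csv(pose_tbl, "results/pose_success.csv", row.names = FALSE)
cat("Pose-reproduction success rates (2 A, heavy atoms):\n")
print(pose_tbl, row.names = FALSE)

# hydrogen-bond occupancies: a stable anchor (Asp-like), a transient donor,
# and an essentially unused one
set.seed(77)
mk_series <- function(p_bound, label) {
  d <- ifelse(runif(2000) < p_bound, runif(2000, 2.6, 3.3), runif(2000, 3.8, 6))
  distance_series(seq(0, 20, length.out = 2000), d, pair_label = label)
}
hb <- list(mk_series(0.995, "Asp OD2"), mk_series(0.48, "Thr OG1"),
           mk_series(0.05, "Gly O"))
occ <- data.frame(
  pair = vapply(hb, attr, character(1), "pair_label"),
  occupancy_pct = vapply(hb, hbond_occupancy, numeric(1)))
write.csv(occ, "results/hbond_occupancy.csv", row.names = FALSE)
cat("\nHydrogen-bond occupancies (3.5 A cutoff):\n")
print(occ, row.names = FALSE)
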