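#!/usr/bin/env Rscript
# Stage 7: chemical-novelty analysis of the confirmed hits.
#
# A synthetic reference panel of known inhibitors (with planted pairwise
# overlaps) is first deduplicated at Tc < 0.6, then each hit's sigma-Tc -
# the sum of its above-0.3 Tanimoto similarities to the panel - is ranked
# against the panel's own sigma-Tc distribution: hits in the bottom tail
# are chemically novel. Ligand efficiencies and a Lipinski check complete
# the hit table.

library(screenval)

# reference panel: 60 "known inhibitors" with internal series similarity
# (chemotype pairs at Tc 0.35-0.55) plus a few near-duplicates above 0.6
prof <- data.frame(i = seq(1, 43, by = 2), j = seq(2, 44, by = 2),
                   tc = c(rep(c(0.35, 0.45, 0.5, 0.55, 0.4), 4), 0.8, 0.9))
panel <- gen_fingerprints(60, overlap_profile = prof, bits_on = 30, seed = 600)
kept <- diversity_filter(panel$fingerprints, tc_max = 0.6)
cat("Diversity filter (Tc < 0.6):", length(panel$fingerprints), "->",
    length(kept), "reference inhibitors\n")

# hits: partial copies of single panel members -> at most one reference
# similarity each, against a panel whose members sit inside chemical series
mk_hit <- function(id, template, n_shared) {
  fresh <- setdiff(0:2047, unlist(lapply(kept, `[[`, "on_bits")))
  fingerprint(id, c(template$on_bits[seq_len(n_shared)],
                    fresh[seq_len(30 - n_shared)]))
}
hits <- list(mk_hit("hit1", kept[[1]], 9),   # Tc 9/51  = 0.176
             mk_hit("hit2", kept[[5]], 12),  # Tc 12/48 = 0.25
             mk_hit("hit3", kept[[9]], 14),  # Tc 14/46 = 0.304
             mk_hit("hit4", kept[[12]], 6))  # Tc 6/54  = 0.111

ref_sums <- vapply(seq_along(kept), function(i) {
  sum_tc(kept[[i]], kept[-i])$sum_tc
}, numeric(1))

novelty <- do.call(rbind, lapply(hits, function(h) {
  p <- sum_tc(h, kept, ref_sum_tc = ref_sums)
  data.frame(molecule_id = p$query_id, sum_tc = round(p$sum_tc, 3),
             n_contributing = p$n_contributing,
             rank = p$rank, percentile = round(p$percentile, 1))
}))
write.csv(novelty, "results/novelty.csv", row.names = FALSE)
cat("\nsigma-Tc novelty profile of the hits (panel mean:",
    round(mean(ref_sums), 2), "):\n")
print(novelty, row.names = FALSE)

# hit table: properties, rule-of-five, ligand efficiency
props <- data.frame(
  molecule_id = paste0("hit", 1:4),
  MW = c(315, 302, 348, 333), logP = c(3.79, 2.9, 3.2, 2.4),
  HBD = c(2, 3, 2, 2), HBA = c(4, 5, 5, 6),
  Kd_M = c(0.35e-6, 0.10e-6, 33.1e-6, 5.0e-6),
  HA = c(23, 22, 25, 24))
ok <- lipinski_filter(props)
props$lipinski <- props$molecule_id %in% ok$molecule_id
props$LE <- round(ligand_efficiency(props$Kd_M, props$HA), 2)
write.csv(props, "results/hit_table.csv", row.names = FALSE)
cat("\nHit table with ligand efficiencies:\n")
print(props[, c("molecule_id", "MW", "logP", "Kd_M", "HA", "LE", "lipinski")],
      row.names = FALSE)
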