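#!/usr/bin/env Rscript
# Stage 3: enrichment metrics, template ranking, candidate selection.
#
# Each structure's score library yields a ROC and its three summary
# metrics: AUC, LogAUC (log10-scaled FPR axis over [0.001, 1], normalised
# by 3 and chance-corrected by 0.145 - the early-enrichment metric) and
# EF1. Structures are ranked by LogAUC with below-median pose reproduction
# demoting a structure outright, and the top 30 scorers of each of the two
# best templates are pooled for experimental validation.

library(screenval)

libs <- read_score_csv("results/scores.csv")
pose <- read.csv("results/pose_success.csv")

metrics <- do.call(rbind, lapply(libs, enrichment_metrics))
metrics <- merge(metrics, pose, by = "structure_id")
write.csv(metrics, "results/enrichment_metrics.csv", row.names = FALSE)
cat("Enrichment metrics per structure:\n")
print(metrics[, c("structure_id", "auc", "logauc", "ef1", "pose_success_pct")],
      row.names = FALSE, digits = 4)

ranked <- rank_ensemble(metrics)
write.csv(ranked, "results/template_ranking.csv", row.names = FALSE)
cat("\nTemplate ranking (LogAUC-first, pose-demotion applied):\n")
print(ranked[, c("structure_id", "logauc", "pose_success_pct", "demoted")],
      row.names = FALSE, digits = 4)

top2 <- ranked$structure_id[1:2]
sel_libs <- libs[vapply(libs, function(l) attr(l, "structure_id") %in% top2,
                        logical(1))]
candidates <- select_top_candidates(sel_libs, n_per = 30)
writeLines(candidates, "results/top_candidates.txt")
cat("\nSelected templates:", paste(top2, collapse = " + "), "->",
    length(candidates), "candidate compounds pooled for NMR screening\n")
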