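#!/usr/bin/env Rscript
# Stage 5 — patient subtyping and symptom characterization.
#
# Patients are clustered on their mean GMV over each hot cluster using
# K-means under the correlation distance (1 - Pearson r), with the number
# of groups chosen by maximizing the mean in-group proportion over
# K = 2..10 (1000 restarts per K). Group differences are then tested on
# the PANSS subscales (P, N, G, TT, PN = P - N) by 10000 label
# permutations, and per-(group, HC) GMV differences by Wilcoxon rank-sum
# tests at the Bonferroni level 0.05 / #HCs.

library(szhc)

seed <- 20260924L
cfg <- pipeline_config(sim = sim_config(seed = seed), seed = seed)
res <- run_pipeline(cfg, "results/pipeline", quiet = TRUE)

sub <- res$subtype$subtypes
message(sprintf("IGP by K: %s",
                paste(names(sub$igp_by_k),
                      sprintf("%.3f", sub$igp_by_k),
                      sep = "=", collapse = "  ")))
message(sprintf("chosen K = %d; group sizes %s", sub$K,
                paste(table(sub$labels), collapse = "/")))

truth <- res$study$truth$true_group_labels
message("recovered groups vs planted groups:")
print(table(recovered = sub$labels, planted = truth))

pw <- res$subtype$perm$pairwise
message("pairwise subscale differences with permutation p < 0.05:")
print(pw[pw$p < 0.05, ], row.names = FALSE)

rs <- res$subtype$rank_sum
message(sprintf("rank-sum (group vs rest) flags at p < %.6f: %d of %d tests",
                rs$threshold[1], sum(rs$significant), nrow(rs)))
print(rs[rs$significant, c("group", "hc", "p")], row.names = FALSE)
message("tables: results/pipeline/labels.tsv, igp_by_k.tsv, subscale_*.tsv, hc_group_tests.tsv")
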