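#!/usr/bin/env Rscript
# Stage 1 — generate the synthetic study.
#
# Emulates the cohort the pipeline was designed around: 72 first-episode
# patients + 73 matched controls, a 200-gene risk panel (5 SNPs per gene
# in strong LD), grey-matter volumes on a 24^3 grid at 1.5 mm with eight
# planted single-gene effect spheres, spatio-temporal expression with one
# co-expressed 20-gene module in (FC, stage 2), and PANSS records with
# three planted patient subgroups. All downstream stages read the
# checkpoints written under results/pipeline/.

library(szhc)

seed <- 20260924L
cfg <- pipeline_config(sim = sim_config(seed = seed), seed = seed)
out <- "results/pipeline"

study <- run_pipeline(cfg, out, upto = "simulate", quiet = TRUE)$study

# export the raw inputs in their interchange formats
dir.create("results/inputs", showWarnings = FALSE, recursive = TRUE)
write_genotypes_vcf(study$genotypes, "results/inputs/genotypes.vcf")
write_plink_raw(study$genotypes, "results/inputs/genotypes.raw.tsv")
utils::write.table(study$covariates, "results/inputs/covariates.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
write_expression_tsv(study$expression, "results/inputs/expression.tsv",
                     "results/inputs/expression_samples.tsv")
utils::write.table(study$panss, "results/inputs/panss.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
write_ground_truth(study$truth, "results/inputs/ground_truth",
                   cfg$sim$voxel_size_mm)

message(sprintf("cohort: %d cases + %d controls; %d SNPs in %d genes",
                cfg$sim$n_cases, cfg$sim$n_controls,
                ncol(study$genotypes$calls), cfg$sim$n_genes))
message(sprintf("planted: %d GMV effect spheres (beta = %.1f), %d-gene module in %s stage %d, subgroups %s",
                nrow(cfg$sim$effect_plan), cfg$sim$effect_plan$beta[1],
                length(cfg$sim$expr_module_plan[[1]]$genes),
                cfg$sim$expr_module_plan[[1]]$region,
                cfg$sim$expr_module_plan[[1]]$stage,
                paste(cfg$sim$subgroup_plan$sizes, collapse = "/")))
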