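#' Pipeline configuration
#'
#' All analysis thresholds in one validated, serializable object. The
#' defaults are the published operating points of the original analysis:
#' association screen at p < 1e-6, co-expression edges at |PCC| > 0.8
#' with 10000 resampling draws, 8 mm FWHM smoothing, cluster-forming
#' threshold 0.2304 under 18-connectivity, K tested over 2..10 with 1000
#' K-means restarts, and 10000 label permutations for the PANSS tests.
#' No stage hard-codes a threshold; everything flows from this object.
#'
#' @param sim a [sim_config()] describing the synthetic cohort
#' @param p_threshold association significance cut
#' @param p_keep per-pair retention cut at regression time
#' @param pcc_threshold co-expression edge threshold
#' @param n_resamples interconnectedness null draws
#' @param fwhm_mm smoothing kernel FWHM
#' @param cluster_threshold cluster-forming threshold on smoothed weights
#' @param connectivity 6, 18 or 26
#' @param k_range candidate group counts
#' @param kmeans_replicates K-means restarts per K
#' @param n_perm PANSS permutation count
#' @param bonferroni_alpha family-wise level for the HC rank-sum tests
#' @param seed global seed; stages derive sub-seeds via [stage_seed()]
#' @return `pipeline_config` object
#' @export
pipeline_config <- function(sim = sim_config(),
                            p_threshold = 1e-6,
                            p_keep = 1e-4,
                            pcc_threshold = 0.8,
                            n_resamples = 10000,
                            fwhm_mm = 8.0,
                            cluster_threshold = 0.2304,
                            connectivity = 18,
                            k_range = 2:10,
                            kmeans_replicates = 1000,
                            n_perm = 10000,
                            bonferroni_alpha = 0.05,
                            seed = 1L) {
  stopifnot(p_threshold > 0, p_threshold <= p_keep, pcc_threshold > 0,
            pcc_threshold < 1, n_resamples > 0, fwhm_mm > 0,
            cluster_threshold > 0, connectivity %in% c(6, 18, 26),
            all(k_range >= 1), kmeans_replicates > 0, n_perm > 0,
            bonferroni_alpha > 0, bonferroni_alpha < 1)
  structure(list(sim = sim, p_threshold = p_threshold, p_keep = p_keep,
                 pcc_threshold = pcc_threshold, n_resamples = n_resamples,
                 fwhm_mm = fwhm_mm, cluster_threshold = cluster_threshold,
                 connectivity = connectivity, k_range = k_range,
                 kmeans_replicates = kmeans_replicates, n_perm = n_perm,
                 bonferroni_alpha = bonferroni_alpha,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Serialize / restore a pipeline configuration (lossless round trip)
#' @param config a `pipeline_config`
#' @param path JSON file
#' @return `path` invisibly; `read_pipeline_config` returns the object
#' @export
write_pipeline_config <- function(config, path) {
  x <- unclass(config)
  x$sim <- unclass(x$sim)
  x$sim$effect_plan <- as.list(x$sim$effect_plan)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  sim <- x$sim
  sim$effect_plan <- as.data.frame(sim$effect_plan,
                                   stringsAsFactors = FALSE)
  mods <- lapply(seq_along(sim$expr_module_plan$region), function(i) list(
    genes = sim$expr_module_plan$genes[[i]],
    region = sim$expr_module_plan$region[i],
    stage = as.integer(sim$expr_module_plan$stage[i]),
    rho = sim$expr_module_plan$rho[i]))
  sp <- sim$subgroup_plan
  simc <- sim_config(
    n_cases = sim$n_cases, n_controls = sim$n_controls,
    n_genes = sim$n_genes, snps_per_gene = sim$snps_per_gene,
    maf_range = sim$maf_range, ld_block_rho = sim$ld_block_rho,
    grid_shape = sim$grid_shape, voxel_size_mm = sim$voxel_size_mm,
    baseline_gmv = sim$baseline_gmv, effect_plan = sim$effect_plan,
    covariate_effects = unlist(sim$covariate_effects),
    noise_sd = sim$noise_sd, expr_module_plan = mods,
    expr_samples_per_stratum = sim$expr_samples_per_stratum,
    subgroup_plan = list(sizes = sp$sizes,
                         gmv_shift = matrix(unlist(sp$gmv_shift),
                                            nrow = length(sp$sizes)),
                         panss_p_shift = sp$panss_p_shift,
                         panss_n_shift = sp$panss_n_shift),
    panss_noise_sd = sim$panss_noise_sd, missing_rate = sim$missing_rate,
    seed = sim$seed)
  pipeline_config(sim = simc, p_threshold = x$p_threshold,
                  p_keep = x$p_keep, pcc_threshold = x$pcc_threshold,
                  n_resamples = x$n_resamples, fwhm_mm = x$fwhm_mm,
                  cluster_threshold = x$cluster_threshold,
                  connectivity = x$connectivity,
                  k_range = as.integer(x$k_range),
                  kmeans_replicates = x$kmeans_replicates,
                  n_perm = x$n_perm, bonferroni_alpha = x$bonferroni_alpha,
                  seed = x$seed)
}

#' Run the full pipeline on a synthetic study
#'
#' Executes simulate -> association -> co-expression -> hot clusters ->
#' subtyping in order, writing each stage's tables under `out_dir` before
#' the next stage starts. Stage results are checkpointed; with
#' `resume = TRUE` a deleted or interrupted stage is recomputed while
#' completed stages are reloaded, yielding identical final outputs. The
#' manifest records the configuration, seed, package version and an md5
#' checksum of every written table.
#'
#' @param config a [pipeline_config()]
#' @param out_dir output directory
#' @param resume reuse existing stage checkpoints when present
#' @param quiet suppress progress messages
#' @param upto last stage to execute ("simulate", "associate",
#'   "coexpress", "hotclust" or "subtype"); earlier stages are resumed
#'   from checkpoints or computed as needed, so the numbered analysis
#'   scripts can drive the pipeline one stage at a time
#' @return invisible list with the stage results computed so far (plus
#'   `manifest` after the final stage)
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir,
                         resume = TRUE, quiet = FALSE,
                         upto = c("subtype", "simulate", "associate",
                                  "coexpress", "hotclust")) {
  stopifnot(inherits(config, "pipeline_config"))
  upto <- match.arg(upto)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ckdir <- file.path(out_dir, "checkpoints")
  dir.create(ckdir, showWarnings = FALSE)
  say <- function(...) if (!quiet) message("[szhc] ", ...)
  stage <- function(name, fn) {
    ck <- file.path(ckdir, paste0(name, ".rds"))
    if (resume && file.exists(ck)) {
      say("stage ", name, ": resumed from checkpoint")
      return(readRDS(ck))
    }
    say("stage ", name, " ...")
    val <- fn()
    saveRDS(val, ck)
    val
  }
  wtab <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    path
  }
  written <- character(0)
  out <- list()

  study <- stage("simulate", function() simulate_study(config$sim))
  out$study <- study
  if (upto == "simulate") return(invisible(out))

  assoc <- stage("associate", function() {
    g <- qc_subjects(study$genotypes)
    g <- qc_markers(g)
    keep <- study$covariates$subject %in% g$subject_ids
    cov <- study$covariates[keep, , drop = FALSE]
    gmvq <- gmv_image_set(study$gmv$data[keep, , drop = FALSE],
                          study$gmv$grid_shape, study$gmv$voxel_size_mm,
                          study$gmv$subject_ids[keep])
    mask <- study$atlas$labels > 0
    res <- snp_voxel_regression(g, gmvq, cov, voxel_mask = mask,
                                p_keep = config$p_keep)
    res <- select_candidates(res, config$p_threshold)
    res$genotypes_qc <- g
    res
  })
  written <- c(written, wtab(assoc$gene_summary, "gene_summary.tsv"),
               wtab(assoc$significant_pairs, "significant_pairs.tsv"))
  out$assoc <- assoc
  if (upto == "associate") return(invisible(out))

  coexp <- stage("coexpress", function() {
    pool <- rownames(study$expression$matrix)
    cand <- intersect(assoc$candidate_genes, pool)
    if (length(cand) < 2) {
      say("fewer than 2 candidate genes in the expression universe; ",
          "interconnectedness suite skipped")
      return(list(table = NULL, candidates = cand))
    }
    tab <- stability_suite(study$expression, cand, pool,
                           thresholds = config$pcc_threshold,
                           n_resamples = config$n_resamples,
                           seed = stage_seed(config$seed, 20L))
    list(table = tab, candidates = cand)
  })
  if (!is.null(coexp$table))
    written <- c(written, wtab(coexp$table, "interconnectedness.tsv"))
  out$coexpress <- coexp
  if (upto == "coexpress") return(invisible(out))

  hc <- stage("hotclust", function() {
    map <- raw_weights(assoc$significant_pairs, study$gmv$grid_shape,
                       study$gmv$voxel_size_mm)
    map <- ld_correct(map, assoc$significant_pairs, assoc$genotypes_qc)
    map <- smooth_weights(map, config$fwhm_mm)
    cl <- extract_clusters(map, config$cluster_threshold,
                           config$connectivity)
    cl <- annotate_clusters(cl, assoc$significant_pairs,
                            assoc$genotypes_qc$snp_meta, study$atlas)
    list(map = map, clusters = cl)
  })
  written <- c(written, wtab(cluster_report(hc$clusters),
                             "cluster_report.tsv"))
  out$hotclust <- hc
  if (upto == "hotclust") return(invisible(out))

  sub <- stage("subtype", function() {
    if (length(hc$clusters) < 2)
      stop("subtype stage needs at least 2 hot clusters")
    patients <- sprintf("case%03d", seq_len(config$sim$n_cases))
    patients <- intersect(patients, study$gmv$subject_ids)
    feat <- extract_hc_features(study$gmv, hc$clusters, patients)
    res <- choose_k(feat, config$k_range, config$kmeans_replicates,
                    seed = stage_seed(config$seed, 30L))
    panss <- study$panss[study$panss$patient %in% patients, , drop = FALSE]
    panss <- panss_subscales(panss)
    perm <- permutation_test_subscales(panss, res$labels, config$n_perm,
                                       seed = stage_seed(config$seed, 31L))
    rank <- hc_group_gmv_test(feat, res$labels, config$bonferroni_alpha)
    list(features = feat, subtypes = res, panss = panss, perm = perm,
         rank_sum = rank)
  })
  written <- c(written,
               wtab(data.frame(patient = rownames(sub$features),
                               group = sub$subtypes$labels), "labels.tsv"),
               wtab(data.frame(K = as.integer(names(sub$subtypes$igp_by_k)),
                               mean_igp = as.numeric(sub$subtypes$igp_by_k)),
                    "igp_by_k.tsv"),
               wtab(sub$perm$group_means, "subscale_group_means.tsv"),
               wtab(sub$perm$pairwise, "subscale_pairwise.tsv"),
               wtab(sub$rank_sum, "hc_group_tests.tsv"))

  cfg_path <- file.path(out_dir, "config.json")
  write_pipeline_config(config, cfg_path)
  manifest <- list(
    package_version = as.character(utils::packageVersion("szhc")),
    seed = config$seed,
    config_md5 = unname(tools::md5sum(cfg_path)),
    outputs = lapply(stats::setNames(written, basename(written)),
                     function(p) unname(tools::md5sum(p))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  say("done: ", length(written), " tables written to ", out_dir)
  out$subtype <- sub
  out$manifest <- manifest
  invisible(out)
}
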