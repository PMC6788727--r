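#' Simulation configuration for the synthetic study generator
#'
#' Collects every knob of the synthetic cohort in one validated object.
#' The defaults emulate the study design the pipeline was built around:
#' 72 drug-naive first-episode patients and 73 matched controls, a panel of
#' risk genes genotyped at several SNPs each in strong within-gene LD, a
#' desk-scale 24 x 24 x 24 voxel grid at 1.5 mm, eight planted single-gene
#' GMV effect spheres, one co-expressed 20-gene module in a single
#' (region, stage) expression stratum, and three patient subgroups with
#' distinct regional GMV profiles and PANSS symptom shifts.
#'
#' @param n_cases,n_controls cohort sizes (defaults 72 / 73)
#' @param n_genes number of risk genes on the panel
#' @param snps_per_gene SNPs genotyped per gene (one LD block per gene)
#' @param maf_range interval in (0, 0.5] from which per-SNP minor allele
#'   frequencies are drawn uniformly
#' @param ld_block_rho exchangeable latent-Gaussian correlation within a
#'   gene's SNP block, in `[0, 1)`
#' @param grid_shape 3 positive integers: voxels per axis
#' @param voxel_size_mm isotropic voxel edge, mm
#' @param baseline_gmv mean grey-matter volume per voxel, arbitrary units
#' @param effect_plan data.frame with columns `gene` (gene symbol),
#'   `snp` (1-based SNP index within the gene), `cx`,`cy`,`cz` (sphere
#'   centre, voxel coordinates), `radius` (voxels), `beta` (GMV change per
#'   minor allele). Spheres from different genes must not overlap.
#' @param covariate_effects named numeric: GMV change per unit `age`,
#'   `sex`, `education` (applied uniformly over the grid)
#' @param noise_sd voxelwise Gaussian noise sd
#' @param expr_module_plan list of planted co-expression modules, each a
#'   list with `genes` (character), `region`, `stage`, `rho`
#'   (within-module correlation)
#' @param expr_samples_per_stratum expression samples per (region, stage)
#' @param subgroup_plan patient subgroup plan: list with `sizes` (summing
#'   to `n_cases`), `gmv_shift` (groups x effect-spheres matrix of GMV
#'   shifts applied inside each sphere), optional `gmv_shift_sd` (same
#'   shape; per-patient Gaussian variability of the shift, constant over
#'   a sphere's voxels — models within-group clinical heterogeneity),
#'   `panss_p_shift`, `panss_n_shift` (per-group per-item shifts on the
#'   positive / negative item blocks)
#' @param panss_noise_sd scale of the half-normal item noise
#' @param missing_rate fraction of genotype calls set missing (QC plumbing)
#' @param seed integer seed; every generator call derives its own
#'   sub-stream from it via [stage_seed()]
#'
#' @return an object of class `sim_config`
#' @export
sim_config <- function(n_cases = 72L,
                       n_controls = 73L,
                       n_genes = 200L,
                       snps_per_gene = 5L,
                       maf_range = c(0.1, 0.4),
                       ld_block_rho = 0.95,
                       grid_shape = c(24L, 24L, 24L),
                       voxel_size_mm = 1.5,
                       baseline_gmv = 2.5,
                       effect_plan = default_effect_plan(),
                       covariate_effects = c(age = -0.01, sex = 0.1,
                                             education = 0.01),
                       noise_sd = 0.2,
                       expr_module_plan = default_module_plan(),
                       expr_samples_per_stratum = 30L,
                       subgroup_plan = default_subgroup_plan(n_cases),
                       panss_noise_sd = 1.5,
                       missing_rate = 0,
                       seed = 1L) {
  cfg <- list(
    n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
    n_genes = as.integer(n_genes), snps_per_gene = as.integer(snps_per_gene),
    maf_range = as.numeric(maf_range), ld_block_rho = ld_block_rho,
    grid_shape = as.integer(grid_shape), voxel_size_mm = voxel_size_mm,
    baseline_gmv = baseline_gmv, effect_plan = effect_plan,
    covariate_effects = covariate_effects, noise_sd = noise_sd,
    expr_module_plan = expr_module_plan,
    expr_samples_per_stratum = as.integer(expr_samples_per_stratum),
    subgroup_plan = subgroup_plan, panss_noise_sd = panss_noise_sd,
    missing_rate = missing_rate, seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_cases, "cases +", x$n_controls, "controls;",
      x$n_genes, "genes x", x$snps_per_gene, "SNPs;grid",
      paste(x$grid_shape, collapse = "x"), "at", x$voxel_size_mm, "mm;",
      nrow(x$effect_plan), "planted effects; seed", x$seed, "\n")
  invisible(x)
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (n_cases <= 0 || n_controls <= 0 || n_genes <= 0 || snps_per_gene <= 0)
      stop("all counts must be positive")
    if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
        maf_range[1] > maf_range[2])
      stop("maf_range must lie within (0, 0.5]")
    if (abs(ld_block_rho) >= 1) stop("|ld_block_rho| must be < 1")
    if (length(grid_shape) != 3 || any(grid_shape <= 0))
      stop("grid_shape must be 3 positive integers")
    if (voxel_size_mm <= 0) stop("voxel_size_mm must be positive")
    if (noise_sd < 0) stop("noise_sd must be non-negative")
    if (missing_rate < 0 || missing_rate >= 1) stop("bad missing_rate")
  })
  ep <- cfg$effect_plan
  if (nrow(ep) > 0) {
    need <- c("gene", "snp", "cx", "cy", "cz", "radius", "beta")
    if (!all(need %in% names(ep))) stop("effect_plan missing columns")
    ctr <- as.matrix(ep[, c("cx", "cy", "cz")])
    lo <- ctr - ep$radius; hi <- ctr + ep$radius   # radius recycles per row
    if (any(lo < 1) || any(t(hi) > cfg$grid_shape))
      stop("effect-plan spheres must lie inside grid_shape")
    if (any(ep$snp < 1) || any(ep$snp > cfg$snps_per_gene))
      stop("effect_plan snp index out of range")
  }
  sp <- cfg$subgroup_plan
  if (!is.null(sp)) {
    if (sum(sp$sizes) != cfg$n_cases)
      stop("subgroup sizes must sum to n_cases")
    if (!is.null(sp$gmv_shift) &&
        (nrow(sp$gmv_shift) != length(sp$sizes) ||
         ncol(sp$gmv_shift) != nrow(ep)))
      stop("gmv_shift must be groups x effect-spheres")
    if (!is.null(sp$gmv_shift_sd) &&
        (!identical(dim(sp$gmv_shift_sd), dim(sp$gmv_shift)) ||
         any(sp$gmv_shift_sd < 0)))
      stop("gmv_shift_sd must be non-negative, groups x effect-spheres")
  }
  for (m in cfg$expr_module_plan) {
    if (!m$region %in% c("FC", "SC", "SM", "TP"))
      stop("module region must be one of FC, SC, SM, TP")
    if (!m$stage %in% 1:3) stop("module stage must be 1, 2 or 3")
    if (m$rho < 0 || m$rho >= 1) stop("module rho must be in [0, 1)")
  }
  invisible(cfg)
}

#' Gene symbols used by the generator
#' @param n number of genes
#' @return character vector `GENE001` ...
#' @export
gene_symbols <- function(n) sprintf("GENE%03d", seq_len(n))

#' Default planted GMV effect plan
#'
#' Eight causal genes, one sphere each (radius 2.5 voxels, beta = 1 GMV
#' unit per minor allele), centred at the eight (6|18)^3 corners of the
#' default 24^3 grid; the 12-voxel centre spacing keeps the smoothed
#' clusters disjoint at the default 8 mm kernel and 0.2304 cluster
#' threshold.
#' @return data.frame effect plan
#' @export
default_effect_plan <- function() {
  corners <- as.matrix(expand.grid(cx = c(6, 18), cy = c(6, 18),
                                   cz = c(6, 18)))
  data.frame(
    gene = gene_symbols(8),
    snp = 3L,
    cx = corners[, 1], cy = corners[, 2], cz = corners[, 3],
    radius = 2.5, beta = 1,
    stringsAsFactors = FALSE)
}

#' Default planted co-expression module plan
#'
#' One 20-gene module (containing the four causal genes) co-expressed at
#' within-module correlation 0.95, planted only in the frontal-cortex
#' samples of developmental stage 2.
#' @return list of module descriptors
#' @export
default_module_plan <- function() {
  list(list(genes = gene_symbols(20), region = "FC", stage = 2L, rho = 0.95))
}

#' Default patient subgroup plan
#'
#' Three patient groups over the eight effect spheres: a smaller,
#' clinically heterogeneous group (n = 14) with a moderate GMV increase on
#' spheres 1–4 plus patient-level regional variability (`gmv_shift_sd` =
#' 0.6 on every sphere), and two larger, internally homogeneous groups
#' (n = 29 each) with strong increases on spheres 5–6 and 7–8
#' respectively — a positive-dominant subtype (+2 per positive PANSS
#' item) and a negative-dominant subtype (+2 per negative item). The
#' unequal sizes and the one heterogeneous group echo how clinical
#' subtypes actually present: group counts differ and one group is
#' diffuse rather than tightly stereotyped.
#' @param n_cases number of patients to split
#' @return subgroup plan list: `sizes`, `gmv_shift` (groups x spheres),
#'   `gmv_shift_sd` (per-patient between-sphere variability by group),
#'   `panss_p_shift`, `panss_n_shift`
#' @export
default_subgroup_plan <- function(n_cases = 72L) {
  n_cases <- as.integer(n_cases)
  n1 <- max(1L, round(n_cases * 14 / 72))
  n2 <- (n_cases - n1 + 1L) %/% 2L
  sizes <- c(n1, n2, n_cases - n1 - n2)
  list(sizes = sizes,
       gmv_shift = rbind(1.5 * c(1, 1, 1, 1, 0, 0, 0, 0),
                         2.5 * c(0, 0, 0, 0, 1, 1, 0, 0),
                         2.5 * c(0, 0, 0, 0, 0, 0, 1, 1)),
       gmv_shift_sd = rbind(rep(0.6, 8), rep(0, 8), rep(0, 8)),
       panss_p_shift = c(0, 2, 0),
       panss_n_shift = c(0, 0, 2))
}
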