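#' Construct a GMV image set
#'
#' Per-subject 3D grey-matter-volume images on one shared grid, stored as a
#' subjects x voxels matrix (column-major voxel order).
#'
#' @param data subjects x voxels numeric matrix
#' @param grid_shape 3 integers
#' @param voxel_size_mm isotropic voxel edge, mm
#' @param subject_ids ordered subject identifiers
#' @return `gmv_image_set` object
#' @export
gmv_image_set <- function(data, grid_shape, voxel_size_mm,
                          subject_ids = rownames(data)) {
  stopifnot(ncol(data) == prod(grid_shape), voxel_size_mm > 0)
  if (any(data < 0)) stop("GMV must be non-negative")
  structure(list(data = data, grid_shape = as.integer(grid_shape),
                 voxel_size_mm = voxel_size_mm, subject_ids = subject_ids),
            class = "gmv_image_set")
}

#' @export
print.gmv_image_set <- function(x, ...) {
  cat("gmv_image_set:", nrow(x$data), "subjects; grid",
      paste(x$grid_shape, collapse = "x"), "at", x$voxel_size_mm, "mm\n")
  invisible(x)
}

#' Extract one subject's volume as a 3D array
#' @param gmv a `gmv_image_set`
#' @param subject subject id or row index
#' @return 3D numeric array
#' @export
gmv_volume <- function(gmv, subject) {
  array(gmv$data[subject, ], dim = gmv$grid_shape)
}

#' Boolean mask of a voxel sphere
#' @keywords internal
sphere_mask <- function(grid_shape, center, radius) {
  idx <- seq_len(prod(grid_shape))
  co <- arrayInd(idx, .dim = grid_shape)
  d2 <- (co[, 1] - center[1])^2 + (co[, 2] - center[2])^2 +
    (co[, 3] - center[3])^2
  array(d2 <= radius^2, dim = grid_shape)
}

#' Simulate grey-matter-volume images with planted SNP effects
#'
#' Each subject's image is
#' `baseline + sum over planted spheres hitting the voxel of beta * allele
#' count + covariate terms + subgroup shift (cases only) + N(0, noise_sd^2)`.
#' Voxels outside every effect sphere carry no genetic signal. Spheres from
#' different genes must be disjoint, which keeps the returned ground-truth
#' masks pairwise disjoint. Values are floored at zero to respect the
#' physical non-negativity of a volume (at the default settings the floor
#' is essentially never reached).
#'
#' @param config a [sim_config()]
#' @param genotypes [simulate_genotypes()] output (same config)
#' @param covariates [simulate_covariates()] output (same config)
#' @return list with `gmv` (a `gmv_image_set`) and `truth` (class
#'   `ground_truth`: causal_snp_ids, causal_gene_ids, true_cluster_masks,
#'   true_group_labels, planted_modules)
#' @export
simulate_gmv <- function(config, genotypes, covariates) {
  stopifnot(inherits(config, "sim_config"),
            inherits(genotypes, "genotype_matrix"))
  if (!identical(genotypes$subject_ids, covariates$subject))
    stop("genotypes and covariates must cover the same subjects, in order")
  ep <- config$effect_plan
  dimg <- config$grid_shape
  nvox <- prod(dimg)
  n <- length(genotypes$subject_ids)

  masks <- list(); snp_cols <- integer(0)
  if (nrow(ep) > 0) {
    for (r in seq_len(nrow(ep))) {
      masks[[r]] <- sphere_mask(dimg, c(ep$cx[r], ep$cy[r], ep$cz[r]),
                                ep$radius[r])
      col <- which(genotypes$snp_meta$gene == ep$gene[r])[ep$snp[r]]
      if (is.na(col)) stop("effect gene not present in genotypes: ", ep$gene[r])
      snp_cols[r] <- col
    }
    cover <- Reduce(`+`, lapply(masks, as.integer))
    genes_at <- lapply(seq_along(masks), function(r)
      ifelse(masks[[r]], ep$gene[r], ""))
    if (any(cover > 1)) {
      over <- which(cover > 1)
      gg <- unique(unlist(lapply(genes_at, function(g) g[over])))
      gg <- setdiff(gg, "")
      if (length(gg) > 1)
        stop("effect spheres from different genes overlap: ",
             paste(gg, collapse = ", "))
    }
  }

  with_seed(stage_seed(config$seed, 3L), {
    vol <- matrix(config$baseline_gmv, n, nvox)
    ce <- config$covariate_effects
    covterm <- ce[["age"]] * covariates$age + ce[["sex"]] * covariates$sex +
      ce[["education"]] * covariates$education
    vol <- vol + covterm          # recycled down columns: one offset/subject
    for (r in seq_along(masks)) {
      v <- which(masks[[r]])
      allele <- genotypes$calls[, snp_cols[r]]
      allele[is.na(allele)] <- 0L
      vol[, v] <- vol[, v] + ep$beta[r] * allele
    }
    # patient subgroup shifts inside the effect spheres (cases only)
    sp <- config$subgroup_plan
    group <- rep(1L, config$n_cases)     # no plan: one undivided group
    if (!is.null(sp)) {
      group <- rep(seq_along(sp$sizes), sp$sizes)
      if (!is.null(sp$gmv_shift) && length(masks) > 0) {
        shift <- sp$gmv_shift[group, , drop = FALSE]
        if (!is.null(sp$gmv_shift_sd)) {
          # per-patient regional variability, constant within a sphere
          jit <- matrix(rnorm(length(group) * length(masks)),
                        length(group), length(masks)) *
            sp$gmv_shift_sd[group, , drop = FALSE]
          shift <- shift + jit
        }
        for (r in seq_along(masks)) {
          v <- which(masks[[r]])
          vol[seq_along(group), v] <- vol[seq_along(group), v] + shift[, r]
        }
      }
    }
    if (config$noise_sd > 0)
      vol <- vol + matrix(rnorm(n * nvox, sd = config$noise_sd), n, nvox)
    vol[vol < 0] <- 0
    rownames(vol) <- genotypes$subject_ids

    truth <- structure(list(
      causal_snp_ids = genotypes$snp_meta$id[snp_cols],
      causal_gene_ids = unique(ep$gene),
      true_cluster_masks = masks,
      true_group_labels = group,
      planted_modules = config$expr_module_plan), class = "ground_truth")
    list(gmv = gmv_image_set(vol, dimg, config$voxel_size_mm,
                             genotypes$subject_ids),
         truth = truth)
  })
}

#' Simulate a voxel-level atlas label image
#'
#' A deterministic synthetic parcellation: the grid is split into eight
#' octants, labelled 1–8 with synthetic region names. Serves as the
#' in-brain mask (all labels > 0) and for naming hot-cluster locations.
#'
#' @param config a [sim_config()]
#' @return list with `labels` (integer 3D array) and `region_names`
#'   (named character vector indexed by label)
#' @export
simulate_atlas <- function(config) {
  dimg <- config$grid_shape
  idx <- seq_len(prod(dimg))
  co <- arrayInd(idx, .dim = dimg)
  half <- dimg / 2
  oct <- 1L + (co[, 1] > half[1]) + 2L * (co[, 2] > half[2]) +
    4L * (co[, 3] > half[3])
  labels <- array(as.integer(oct), dim = dimg)
  nm <- apply(expand.grid(c("L", "R"), c("A", "P"), c("I", "S")), 1,
              paste, collapse = "")
  list(labels = labels, region_names = stats::setNames(paste0("Octant_", nm),
                                                       as.character(1:8)))
}
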