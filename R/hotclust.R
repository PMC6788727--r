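#' Raw voxel weights from significant SNP-voxel pairs
#'
#' Each voxel is weighted by the number of distinct SNPs significantly
#' associated with its GMV (duplicate pair records count once).
#'
#' @param sig_pairs data.frame with columns `snp` and either `voxel`
#'   (linear index) or `i`,`j`,`k`
#' @param grid_shape 3 integers
#' @param voxel_size_mm isotropic voxel edge, mm
#' @return `voxel_weight_map`: list with `raw` (3D array), `corrected`,
#'   `smoothed` (NULL until computed), `voxel_size_mm`, `fwhm_mm`
#' @export
raw_weights <- function(sig_pairs, grid_shape, voxel_size_mm = 1.5) {
  grid_shape <- as.integer(grid_shape)
  raw <- array(0, dim = grid_shape)
  if (nrow(sig_pairs) > 0) {
    v <- if ("voxel" %in% names(sig_pairs)) as.integer(sig_pairs$voxel)
         else vox_linear(as.matrix(sig_pairs[, c("i", "j", "k")]), grid_shape)
    if (any(v < 1) || any(v > prod(grid_shape)))
      stop("voxel index outside grid")
    u <- !duplicated(paste(sig_pairs$snp, v))
    tab <- table(v[u])
    raw[as.integer(names(tab))] <- as.integer(tab)
  }
  structure(list(raw = raw, corrected = NULL, smoothed = NULL,
                 voxel_size_mm = voxel_size_mm, fwhm_mm = NULL),
            class = "voxel_weight_map")
}

#' @export
print.voxel_weight_map <- function(x, ...) {
  cat("voxel_weight_map:", paste(dim(x$raw), collapse = "x"), "grid;",
      sum(x$raw > 0), "weighted voxels; raw mass", sum(x$raw))
  if (!is.null(x$corrected)) cat("; corrected mass",
                                 round(sum(x$corrected), 3))
  if (!is.null(x$smoothed)) cat("; smoothed (FWHM", x$fwhm_mm, "mm)")
  cat("\n"); invisible(x)
}

#' Effective number of independent tests (Li–Ji estimator)
#'
#' Given the eigenvalues of a correlation matrix of `m` variables, the
#' effective number is `sum over i of f(lambda_i)` with
#' `f(x) = I(x >= 1) + (x - floor(x))`. Perfect correlation gives 1,
#' independence gives m. Eigenvalues are rounded to 8 decimals first so
#' that analytically integer eigenvalues (e.g. exactly duplicated SNPs)
#' are not split by floating-point jitter.
#'
#' @param R correlation matrix
#' @return effective number of independent variables
#' @export
li_ji_meff <- function(R) {
  m <- nrow(R)
  if (m == 1) return(1)
  lambda <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  lambda <- round(pmax(lambda, 0), 8)
  sum((lambda >= 1) + (lambda - floor(lambda)))
}

#' LD-correct voxel weights
#'
#' Within each voxel, its significant SNPs are grouped by chromosome; the
#' contribution of a chromosome is the effective number of independent
#' SNPs ([li_ji_meff()]) computed from the SNPs' genotype correlation
#' matrix over subjects with complete calls; chromosomes contribute
#' additively. SNPs on distinct chromosomes are never corrected against
#' each other.
#'
#' @param map a `voxel_weight_map` from [raw_weights()]
#' @param sig_pairs the significant pairs used to build `map`
#' @param genotypes `genotype_matrix` carrying the SNPs with chromosome
#'   annotation
#' @return the map with `corrected` filled in (`corrected <= raw`)
#' @export
ld_correct <- function(map, sig_pairs, genotypes) {
  stopifnot(inherits(map, "voxel_weight_map"),
            inherits(genotypes, "genotype_matrix"))
  dimg <- dim(map$raw)
  corrected <- array(0, dim = dimg)
  if (nrow(sig_pairs) == 0) { map$corrected <- corrected; return(map) }
  if (!all(sig_pairs$snp %in% genotypes$snp_meta$id))
    stop("sig_pairs contain SNPs absent from genotypes")
  v <- if ("voxel" %in% names(sig_pairs)) as.integer(sig_pairs$voxel)
       else vox_linear(as.matrix(sig_pairs[, c("i", "j", "k")]), dimg)
  snps_by_vox <- split(sig_pairs$snp, v)
  cache <- new.env(parent = emptyenv())
  chrom <- stats::setNames(genotypes$snp_meta$chrom, genotypes$snp_meta$id)
  for (vv in names(snps_by_vox)) {
    ss <- unique(snps_by_vox[[vv]])
    key <- paste(sort(ss), collapse = ";")
    w <- if (!is.null(cache[[key]])) cache[[key]] else {
      tot <- 0
      for (cs in split(ss, chrom[ss])) {
        if (length(cs) == 1) { tot <- tot + 1; next }
        calls <- genotypes$calls[, cs, drop = FALSE]
        ok <- stats::complete.cases(calls)
        if (sum(ok) < 2) {
          warning("fewer than 2 complete subjects for a SNP group; ",
                  "LD correction skipped there", call. = FALSE)
          tot <- tot + length(cs); next
        }
        R <- suppressWarnings(stats::cor(calls[ok, , drop = FALSE]))
        R[!is.finite(R)] <- 0; diag(R) <- 1
        tot <- tot + min(li_ji_meff(R), length(cs))
      }
      cache[[key]] <- tot
      tot
    }
    corrected[as.integer(vv)] <- w
  }
  map$corrected <- corrected
  map
}

#' One-dimensional truncated Gaussian kernel, unit sum
#' @keywords internal
gaussian_kernel_1d <- function(sigma, truncate = 4) {
  r <- ceiling(truncate * sigma)
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k / sum(k)
}

#' Zero-padded 1D convolution along the first axis of an unfolded array
#' @keywords internal
conv_axis <- function(m, kernel) {
  # m: n x rest matrix; kernel centred, odd length; zero padding outside
  n <- nrow(m); r <- (length(kernel) - 1L) / 2L
  out <- matrix(0, n, ncol(m))
  for (d in seq(-r, r)) {
    w <- kernel[d + r + 1L]
    src <- seq_len(n) + d
    ok <- src >= 1L & src <= n
    out[ok, ] <- out[ok, ] + w * m[src[ok], , drop = FALSE]
  }
  out
}

#' Smooth a 3D array with an isotropic Gaussian kernel
#'
#' Separable convolution with a unit-sum 1D kernel along each axis,
#' truncated at 4 sigma, zero-padded at the boundaries (so total mass is
#' preserved away from the boundary and never increased).
#'
#' @param a 3D numeric array
#' @param sigma_vox kernel standard deviation in voxel units
#' @return smoothed 3D array
#' @export
gaussian_smooth_3d <- function(a, sigma_vox) {
  stopifnot(length(dim(a)) == 3, sigma_vox >= 0)
  if (sigma_vox == 0) return(a)
  k <- gaussian_kernel_1d(sigma_vox)
  d <- dim(a)
  a <- array(conv_axis(matrix(a, d[1], d[2] * d[3]), k), d)
  a <- aperm(a, c(2, 1, 3))
  a <- array(conv_axis(matrix(a, d[2], d[1] * d[3]), k), c(d[2], d[1], d[3]))
  a <- aperm(a, c(2, 1, 3))
  a <- aperm(a, c(3, 2, 1))
  a <- array(conv_axis(matrix(a, d[3], d[2] * d[1]), k), c(d[3], d[2], d[1]))
  aperm(a, c(3, 2, 1))
}

#' Smooth the (corrected) voxel weight map
#'
#' Applies an isotropic Gaussian of the given full-width at half-maximum;
#' `sigma_voxels = fwhm_mm / (2 sqrt(2 ln 2)) / voxel_size_mm`. Operates
#' on the LD-corrected map when present, else on the raw map.
#'
#' @param map a `voxel_weight_map`
#' @param fwhm_mm kernel FWHM in millimetres (default 8)
#' @return the map with `smoothed` and `fwhm_mm` filled in
#' @export
smooth_weights <- function(map, fwhm_mm = 8.0) {
  stopifnot(inherits(map, "voxel_weight_map"))
  if (fwhm_mm <= 0) stop("fwhm_mm must be positive")
  src <- map$corrected %||% map$raw
  sigma <- fwhm_to_sigma(fwhm_mm, map$voxel_size_mm)
  map$smoothed <- gaussian_smooth_3d(src, sigma)
  map$fwhm_mm <- fwhm_mm
  map
}

neighbor_offsets <- function(connectivity) {
  off <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  nz <- rowSums(abs(off))
  switch(as.character(connectivity),
         "6" = off[nz == 1, , drop = FALSE],
         "18" = off[nz >= 1 & nz <= 2, , drop = FALSE],
         "26" = off[nz >= 1, , drop = FALSE],
         stop("connectivity must be 6, 18 or 26"))
}

#' Extract hot clusters from a smoothed weight map
#'
#' Voxels with smoothed weight strictly exceeding `threshold` are
#' partitioned into maximal connected components under the chosen
#' connectivity (default 18: voxels sharing a face or an edge are
#' neighbours; corner-only contact does not connect). Clusters are ranked
#' by decreasing maximum voxel weight and named HC1, HC2, ...
#'
#' @param map a `voxel_weight_map` with `smoothed` present
#' @param threshold cluster-forming threshold (strict >)
#' @param connectivity 6, 18 or 26
#' @return list of `hot_cluster` objects (possibly empty): each has `id`,
#'   `rank`, `voxels` (linear indices), `ijk`, `size`, `max_weight`
#' @export
extract_clusters <- function(map, threshold = 0.2304, connectivity = 18) {
  stopifnot(inherits(map, "voxel_weight_map"))
  if (is.null(map$smoothed)) stop("smooth the map before extracting clusters")
  sm <- map$smoothed; dimg <- dim(sm)
  sup <- which(sm > threshold)
  if (length(sup) == 0) return(list())
  lin2sup <- integer(prod(dimg)); lin2sup[sup] <- seq_along(sup)
  co <- vox_ijk(sup, dimg)
  off <- neighbor_offsets(connectivity)
  # union-find over supra-threshold voxels
  parent <- seq_along(sup)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (o in seq_len(nrow(off))) {
    ni <- co[, 1] + off[o, 1]; nj <- co[, 2] + off[o, 2]
    nk <- co[, 3] + off[o, 3]
    inside <- ni >= 1 & ni <= dimg[1] & nj >= 1 & nj <= dimg[2] &
      nk >= 1 & nk <= dimg[3]
    nlin <- (nk[inside] - 1L) * dimg[1] * dimg[2] +
      (nj[inside] - 1L) * dimg[1] + ni[inside]
    a <- which(inside)[lin2sup[nlin] > 0]
    b <- lin2sup[nlin][lin2sup[nlin] > 0]
    for (e in seq_along(a)) {
      ra <- find(a[e]); rb <- find(b[e])
      if (ra != rb) parent[ra] <- rb
    }
  }
  root <- vapply(seq_along(sup), find, integer(1))
  comps <- unname(split(seq_along(sup), root))
  maxw <- vapply(comps, function(ix) max(sm[sup[ix]]), numeric(1))
  ord <- order(-maxw, vapply(comps, function(ix) min(sup[ix]), integer(1)))
  lapply(seq_along(ord), function(r) {
    ix <- comps[[ord[r]]]
    structure(list(id = paste0("HC", r), rank = r, voxels = sup[ix],
                   ijk = co[ix, , drop = FALSE], size = length(ix),
                   max_weight = maxw[ord[r]], grid_shape = dimg),
              class = "hot_cluster")
  })
}

#' @export
print.hot_cluster <- function(x, ...) {
  cat(x$id, ": ", x$size, " voxels, max weight ", round(x$max_weight, 4),
      if (!is.null(x$atlas_label)) paste0(", ", x$atlas_label) else "",
      if (!is.null(x$associated_genes))
        paste0(" [", paste(x$associated_genes, collapse = ","), "]") else "",
      "\n", sep = "")
  invisible(x)
}

#' Annotate hot clusters with genes and atlas regions
#'
#' A cluster's associated genes are the genes of SNPs whose significant
#' voxels intersect the cluster; its atlas label is the modal atlas region
#' over the cluster's voxels, with the full label composition reported.
#'
#' @param clusters list of `hot_cluster`
#' @param sig_pairs significant pairs (with `snp` and voxel columns)
#' @param snp_meta per-SNP annotation (id, gene)
#' @param atlas list with `labels` (integer 3D array on the same grid)
#'   and `region_names` (named by label)
#' @return the clusters, each with `associated_genes`, `atlas_label`,
#'   `label_fractions` added
#' @export
annotate_clusters <- function(clusters, sig_pairs, snp_meta, atlas) {
  if (length(clusters) == 0) return(clusters)
  dimg <- dim(atlas$labels)
  for (cl in clusters)
    if (!is.null(cl$grid_shape) &&
        !identical(as.integer(cl$grid_shape), as.integer(dimg)))
      stop("atlas grid mismatch: clusters on ",
           paste(cl$grid_shape, collapse = "x"), ", atlas on ",
           paste(dimg, collapse = "x"))
  v <- if ("voxel" %in% names(sig_pairs)) as.integer(sig_pairs$voxel)
       else vox_linear(as.matrix(sig_pairs[, c("i", "j", "k")]), dimg)
  gene_of <- stats::setNames(snp_meta$gene, snp_meta$id)
  lapply(clusters, function(cl) {
    hit <- v %in% cl$voxels
    cl$associated_genes <- sort(unique(gene_of[sig_pairs$snp[hit]]))
    lab <- atlas$labels[cl$voxels]
    tab <- sort(table(lab), decreasing = TRUE)
    top <- names(tab)[1]
    cl$atlas_label <- unname(atlas$region_names[top] %||% top)
    fr <- as.numeric(tab) / sum(tab)
    names(fr) <- unname(atlas$region_names[names(tab)] %||% names(tab))
    cl$label_fractions <- fr
    cl
  })
}

#' Cluster report table
#'
#' One row per hot cluster: id, size, max weight, atlas region and
#' associated genes — the shape of the published cluster table.
#'
#' @param clusters annotated `hot_cluster` list
#' @return data.frame
#' @export
cluster_report <- function(clusters) {
  if (length(clusters) == 0)
    return(data.frame(id = character(0), size = integer(0),
                      max_weight = numeric(0), atlas_label = character(0),
                      genes = character(0)))
  do.call(rbind, lapply(clusters, function(cl) data.frame(
    id = cl$id, size = cl$size, max_weight = cl$max_weight,
    atlas_label = cl$atlas_label %||% NA_character_,
    genes = paste(cl$associated_genes %||% character(0), collapse = ";"),
    stringsAsFactors = FALSE)))
}
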