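test_that("raw weights count distinct SNPs per voxel", {
  pairs <- data.frame(snp = c("s1", "s2", "s1", "s1"),
                      i = c(2L, 2L, 3L, 2L), j = 2L, k = 2L,
                      stringsAsFactors = FALSE)
  # (s1, v) listed twice: set semantics, counted once
  map <- raw_weights(pairs, c(4L, 4L, 4L), 1.5)
  expect_equal(map$raw[2, 2, 2], 2)
  expect_equal(map$raw[3, 2, 2], 1)
  expect_equal(sum(map$raw), 3)
  empty <- raw_weights(pairs[0, ], c(4L, 4L, 4L), 1.5)
  expect_true(all(empty$raw == 0))
  bad <- data.frame(snp = "s1", i = 9L, j = 1L, k = 1L)
  expect_error(raw_weights(bad, c(4L, 4L, 4L), 1.5))
})

test_that("Li-Ji effective count hits its analytic anchors", {
  expect_equal(li_ji_meff(matrix(c(1, 1, 1, 1), 2, 2)), 1)   # perfect LD
  expect_equal(li_ji_meff(diag(4)), 4)                       # independence
  # exchangeable rho = 0.5, m = 5: eigenvalues exactly 3, 0.5 x4
  R <- matrix(0.5, 5, 5); diag(R) <- 1
  lambda <- round(eigen(R, only.values = TRUE)$values, 8)
  expect_equal(li_ji_meff(R),
               sum((lambda >= 1) + (lambda - floor(lambda))),
               tolerance = 1e-10)
  expect_equal(li_ji_meff(R), 3)                             # f(3) + 4*f(0.5)
})

test_that("LD correction collapses same-chromosome duplicates and spares distinct chromosomes", {
  n <- 60L
  set.seed(8)
  g <- as.integer(rbinom(n, 2, 0.4))
  same <- genotype_matrix(
    matrix(c(g, g), n, 2, dimnames = list(NULL, c("sA", "sB"))),
    data.frame(id = c("sA", "sB"), gene = "G1", chrom = 7L,
               pos = c(100L, 200L), stringsAsFactors = FALSE),
    sprintf("sub%02d", 1:n))
  pairs <- data.frame(snp = c("sA", "sB"), i = 2L, j = 2L, k = 2L,
                      stringsAsFactors = FALSE)
  map <- raw_weights(pairs, c(4L, 4L, 4L), 1.5)
  cor_same <- ld_correct(map, pairs, same)
  expect_equal(cor_same$raw[2, 2, 2], 2)
  expect_equal(cor_same$corrected[2, 2, 2], 1)    # one effective SNP
  g2 <- as.integer(rbinom(n, 2, 0.4))
  diff_chr <- genotype_matrix(
    matrix(c(g, g2), n, 2, dimnames = list(NULL, c("sA", "sB"))),
    data.frame(id = c("sA", "sB"), gene = c("G1", "G2"), chrom = c(7L, 9L),
               pos = c(100L, 200L), stringsAsFactors = FALSE),
    sprintf("sub%02d", 1:n))
  cor_diff <- ld_correct(map, pairs, diff_chr)
  expect_equal(cor_diff$corrected[2, 2, 2], 2)    # no cross-chromosome pooling
  expect_true(all(cor_diff$corrected <= cor_diff$raw + 1e-9))
})

test_that("LD correction agrees with the eigenvalue oracle on simulated blocks", {
  cfg <- sim_config(n_cases = 300L, n_controls = 300L, n_genes = 1L,
                    snps_per_gene = 5L, ld_block_rho = 0.5,
                    effect_plan = default_effect_plan()[0, ],
                    expr_module_plan = list(), subgroup_plan = NULL,
                    seed = 15L)
  geno <- simulate_genotypes(cfg)
  pairs <- data.frame(snp = geno$snp_meta$id, i = 3L, j = 3L, k = 3L,
                      stringsAsFactors = FALSE)
  map <- ld_correct(raw_weights(pairs, c(6L, 6L, 6L), 1.5), pairs, geno)
  R <- cor(geno$calls)
  lambda <- pmax(eigen(R, symmetric = TRUE, only.values = TRUE)$values, 0)
  lambda <- round(lambda, 8)
  m_eff <- sum((lambda >= 1) + (lambda - floor(lambda)))
  expect_equal(map$corrected[3, 3, 3], m_eff, tolerance = 1e-8)
  expect_lt(map$corrected[3, 3, 3], 5)
})

test_that("FWHM-to-sigma conversion and the smoothing kernel are exact", {
  expect_equal(fwhm_to_sigma(8, 1.5), 8 / (2 * sqrt(2 * log(2))) / 1.5,
               tolerance = 1e-12)
  expect_equal(fwhm_to_sigma(8, 1.5), 2.265, tolerance = 1e-3)
  # unit impulse: mass preserved, symmetric about the centre
  a <- array(0, c(21, 21, 21)); a[11, 11, 11] <- 1
  s <- gaussian_smooth_3d(a, fwhm_to_sigma(8, 1.5))
  expect_equal(sum(s), 1, tolerance = 1e-6)
  expect_equal(s[10, 11, 11], s[12, 11, 11], tolerance = 1e-12)
  expect_equal(s[11, 10, 11], s[11, 11, 12], tolerance = 1e-12)
  # constant interior stays constant away from the boundary
  b <- array(1, c(31, 31, 31))
  sb <- gaussian_smooth_3d(b, 2)
  expect_equal(sb[16, 16, 16], 1, tolerance = 1e-6)
  # zero padding can only lose mass
  expect_lte(sum(sb), sum(b))
  expect_error(smooth_weights(raw_weights(
    data.frame(snp = "s", i = 1L, j = 1L, k = 1L), c(3L, 3L, 3L), 1.5),
    fwhm_mm = 0), "positive")
})

test_that("cluster extraction matches BFS flood fill across connectivities", {
  set.seed(9)
  for (rep in 1:5) {
    arr <- array(runif(10 * 9 * 8), c(10, 9, 8))
    arr[arr < 0.65] <- 0
    map <- structure(list(raw = arr, corrected = NULL, smoothed = arr,
                          voxel_size_mm = 1.5, fwhm_mm = 8),
                     class = "voxel_weight_map")
    for (conn in c(6, 18, 26)) {
      cl <- extract_clusters(map, threshold = 0.7, connectivity = conn)
      ora <- oracle_flood_fill(arr, 0.7, conn)
      expect_equal(length(cl), length(ora))
      got <- lapply(cl, function(x) sort(x$voxels))
      expect_setequal(lapply(got, paste, collapse = ","),
                      lapply(ora, paste, collapse = ","))
      # partition property: disjoint, union = supra-threshold set
      all_vox <- unlist(got)
      expect_equal(sort(all_vox), sort(which(arr > 0.7)))
      expect_false(any(duplicated(all_vox)))
    }
  }
})

test_that("corner-contact separates at 18-connectivity and joins at 26", {
  arr <- array(0, c(4, 4, 4))
  arr[1, 1, 1] <- 1; arr[2, 2, 2] <- 1     # share only a corner
  map <- structure(list(raw = arr, corrected = NULL, smoothed = arr,
                        voxel_size_mm = 1.5, fwhm_mm = 8),
                   class = "voxel_weight_map")
  expect_length(extract_clusters(map, 0.5, 18), 2)
  expect_length(extract_clusters(map, 0.5, 26), 1)
  edge <- array(0, c(4, 4, 4))
  edge[1, 1, 1] <- 1; edge[2, 2, 1] <- 1   # share an edge
  mape <- map; mape$smoothed <- edge
  expect_length(extract_clusters(mape, 0.5, 18), 1)
  expect_length(extract_clusters(mape, 0.5, 6), 2)
})

test_that("clusters are ranked by decreasing maximum weight and named HC1..", {
  arr <- array(0, c(8, 8, 8))
  arr[2, 2, 2] <- 0.5                      # weaker blob
  arr[6, 6, 6] <- 0.9; arr[6, 6, 7] <- 0.4 # stronger blob
  map <- structure(list(raw = arr, corrected = NULL, smoothed = arr,
                        voxel_size_mm = 1.5, fwhm_mm = 8),
                   class = "voxel_weight_map")
  cl <- extract_clusters(map, 0.3, 18)
  expect_equal(vapply(cl, `[[`, character(1), "id"), c("HC1", "HC2"))
  expect_equal(cl[[1]]$max_weight, 0.9)
  expect_equal(cl[[1]]$size, 2)
  expect_length(extract_clusters(map, 2.0, 18), 0)  # all sub-threshold
})

test_that("annotation assigns genes by intersecting voxels and the modal atlas label", {
  arr <- array(0, c(6, 6, 6))
  arr[2:4, 2, 2] <- 1                      # 3-voxel cluster straddling labels
  map <- structure(list(raw = arr, corrected = NULL, smoothed = arr,
                        voxel_size_mm = 1.5, fwhm_mm = 8),
                   class = "voxel_weight_map")
  cl <- extract_clusters(map, 0.5, 18)
  labels <- array(1L, c(6, 6, 6)); labels[4:6, , ] <- 2L
  atlas <- list(labels = labels,
                region_names = c("1" = "RegionA", "2" = "RegionB"))
  pairs <- data.frame(snp = c("sX", "sY"),
                      i = c(2L, 5L), j = c(2L, 5L), k = c(2L, 5L),
                      stringsAsFactors = FALSE)
  meta <- data.frame(id = c("sX", "sY"), gene = c("GENEX", "GENEY"),
                     chrom = 1L, pos = 1:2, stringsAsFactors = FALSE)
  out <- annotate_clusters(cl, pairs, meta, atlas)
  expect_equal(out[[1]]$associated_genes, "GENEX")   # sY outside cluster
  expect_equal(out[[1]]$atlas_label, "RegionA")      # 2 of 3 voxels
  expect_equal(unname(out[[1]]$label_fractions["RegionA"]), 2 / 3,
               tolerance = 1e-12)
  bad_atlas <- list(labels = array(1L, c(5, 5, 5)),
                    region_names = c("1" = "RegionA"))
  expect_error(annotate_clusters(cl, pairs, meta, bad_atlas), "mismatch")
})

test_that("adding significant pairs never decreases any raw weight", {
  set.seed(10)
  d <- c(6L, 6L, 6L)
  p1 <- data.frame(snp = sprintf("s%d", 1:20),
                   i = sample(6, 20, TRUE), j = sample(6, 20, TRUE),
                   k = sample(6, 20, TRUE), stringsAsFactors = FALSE)
  p2 <- rbind(p1, data.frame(snp = "s99", i = 3L, j = 3L, k = 3L))
  w1 <- raw_weights(p1, d, 1.5)$raw
  w2 <- raw_weights(p2, d, 1.5)$raw
  expect_true(all(w2 >= w1))
})
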