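make_geno <- function(calls) {
  n_snp <- ncol(calls)
  genotype_matrix(
    calls,
    data.frame(id = sprintf("s%02d", seq_len(n_snp)),
               gene = sprintf("G%02d", seq_len(n_snp)),
               chrom = 1L, pos = seq_len(n_snp) * 100L,
               stringsAsFactors = FALSE),
    sprintf("sub%02d", seq_len(nrow(calls))))
}

test_that("subject QC removes low call rates with a strict-below boundary", {
  calls <- matrix(1L, 4, 100)
  calls[1, 1:10] <- NA_integer_   # rate 0.90: removed
  calls[2, 1:3] <- NA_integer_    # rate 0.97 exactly: retained
  g <- make_geno(calls)
  out <- qc_subjects(g)
  expect_setequal(out$subject_ids, g$subject_ids[2:4])
  expect_identical(out$subject_ids, g$subject_ids[2:4])  # order preserved
  clean <- qc_subjects(make_geno(matrix(1L, 3, 10)))
  expect_equal(nrow(clean$calls), 3)
  expect_error(qc_subjects(make_geno(matrix(NA_integer_, 2, 10))), "all subjects")
})

test_that("marker QC applies the MAF and missingness rules at their boundaries", {
  # calls [0,0,1,1,2]: 4 minor alleles of 10 -> MAF 0.4, retained
  calls <- cbind(c(0L, 0L, 1L, 1L, 2L),        # MAF 0.40 keep
                 c(0L, 0L, 0L, 0L, 1L),        # MAF 0.10 keep
                 c(0L, 0L, 0L, 0L, 0L),        # MAF 0    drop
                 c(1L, 0L, 0L, 0L, 0L))        # MAF 0.10 but missing below
  g <- make_geno(calls)
  expect_equal(unname(snp_maf(calls)[1]), 0.4)
  out <- qc_markers(g, hwe_alpha = 0)   # isolate MAF/missingness rules
  expect_true(all(c("s01", "s02") %in% out$snp_meta$id))
  expect_false("s03" %in% out$snp_meta$id)
  # MAF exactly at the threshold is excluded (rule is <= 0.05)
  n <- 100
  at_thr <- c(rep(0L, 90), rep(1L, 10))        # MAF exactly 0.05
  calls2 <- cbind(at_thr, c(rep(0L, 50), rep(1L, 40), rep(2L, 10)))
  out2 <- qc_markers(make_geno(matrix(calls2, n, 2)), hwe_alpha = 0)
  expect_false("s01" %in% out2$snp_meta$id)
  # > 5% missing removed; exactly 5% kept
  m1 <- c(rep(NA_integer_, 6), rep(1L, 94))    # 6% missing: drop
  m2 <- c(rep(NA_integer_, 5), rep(1L, 45), rep(0L, 50))  # 5%: keep
  out3 <- qc_markers(make_geno(cbind(m1, m2)), hwe_alpha = 0)
  expect_identical(out3$snp_meta$id, "s02")
})

test_that("exact HWE test matches full enumeration and handles the balanced case", {
  # (AA=25, Aa=50, aa=25) is the modal HW configuration: p close to 1
  expect_equal(hwe_exact_p(25, 50, 25), oracle_hwe(25, 50, 25),
               tolerance = 1e-12)
  expect_gt(hwe_exact_p(25, 50, 25), 0.5)
  cases <- list(c(40, 40, 20), c(80, 15, 5), c(50, 0, 50), c(10, 80, 10),
                c(99, 1, 0), c(3, 5, 2))
  for (cs in cases)
    expect_equal(hwe_exact_p(cs[1], cs[2], cs[3]),
                 oracle_hwe(cs[1], cs[2], cs[3]), tolerance = 1e-10)
  # gross heterozygote excess is detected at the QC threshold
  expect_lt(hwe_exact_p(0, 100, 0), 1e-6)
})

test_that("marker QC is idempotent", {
  cfg <- tiny_config(seed = 61L, missing_rate = 0.03)
  g <- simulate_genotypes(cfg)
  once <- qc_markers(g)
  twice <- qc_markers(once)
  expect_identical(once$calls, twice$calls)
  expect_identical(once$snp_meta, twice$snp_meta)
})

test_that("regression matches the explicit normal-equations oracle", {
  for (seed in c(1L, 2L)) {
    set.seed(seed)
    n <- if (seed == 1L) 20L else 50L
    g <- rbinom(n, 2, 0.3)
    if (var(g) == 0) g[1] <- 1L
    age <- runif(n, 16, 45); sex <- rbinom(n, 1, 0.5); edu <- runif(n, 6, 18)
    y <- 3 + 0.4 * g - 0.01 * age + 0.2 * sex + rnorm(n, sd = 0.5)
    geno <- make_geno(matrix(as.integer(g), n, 1))
    gmv <- gmv_image_set(matrix(y, n, 1), c(1L, 1L, 1L), 1.5,
                         geno$subject_ids)
    cov <- data.frame(subject = geno$subject_ids, age = age, sex = sex,
                      education = edu, is_case = 1L)
    res <- snp_voxel_regression(geno, gmv, cov, keep_full = TRUE)
    ora <- oracle_ols(y, g, age, sex, edu)
    expect_equal(unname(res$beta[1, 1]), unname(ora$beta), tolerance = 1e-8)
    expect_equal(unname(res$t[1, 1]), unname(ora$t), tolerance = 1e-8)
    expect_equal(unname(res$p[1, 1]), unname(ora$p), tolerance = 1e-8)
  }
})

test_that("a noiseless planted effect is estimated exactly and shifts only the intercept", {
  set.seed(3)
  n <- 30L
  g <- as.integer(rbinom(n, 2, 0.4))
  age <- runif(n, 16, 45); sex <- rbinom(n, 1, 0.5); edu <- runif(n, 6, 18)
  y <- 1.0 + 0.5 * g
  geno <- make_geno(matrix(g, n, 1))
  cov <- data.frame(subject = geno$subject_ids, age = age, sex = sex,
                    education = edu, is_case = 1L)
  fit1 <- snp_voxel_regression(geno, gmv_image_set(matrix(y, n, 1),
                                                   c(1L, 1L, 1L), 1.5,
                                                   geno$subject_ids),
                               cov, keep_full = TRUE)
  expect_equal(unname(fit1$beta[1, 1]), 0.5, tolerance = 1e-10)
  expect_lt(fit1$p[1, 1], 1e-12)
  # adding a constant to every GMV value leaves beta1, t and p unchanged
  set.seed(4)
  y2 <- y + abs(rnorm(n, sd = 0.3))
  f_a <- snp_voxel_regression(geno, gmv_image_set(matrix(y2, n, 1),
                                                  c(1L, 1L, 1L), 1.5,
                                                  geno$subject_ids),
                              cov, keep_full = TRUE)
  f_b <- snp_voxel_regression(geno, gmv_image_set(matrix(y2 + 5, n, 1),
                                                  c(1L, 1L, 1L), 1.5,
                                                  geno$subject_ids),
                              cov, keep_full = TRUE)
  expect_equal(unname(f_a$beta[1, 1]), unname(f_b$beta[1, 1]), tolerance = 1e-10)
  expect_equal(unname(f_a$t[1, 1]), unname(f_b$t[1, 1]), tolerance = 1e-10)
  expect_equal(unname(f_a$p[1, 1]), unname(f_b$p[1, 1]), tolerance = 1e-10)
})

test_that("degenerate designs return missing statistics rather than fits", {
  n <- 6L
  set.seed(5)
  cov <- data.frame(subject = sprintf("sub%02d", 1:n),
                    age = runif(n, 16, 45), sex = rbinom(n, 1, 0.5),
                    education = runif(n, 6, 18), is_case = 1L)
  y <- matrix(2 + rnorm(n, sd = 0.3), n, 1)
  const <- make_geno(matrix(1L, n, 1))             # constant genotype
  r1 <- snp_voxel_regression(const, gmv_image_set(y, c(1L, 1L, 1L), 1.5,
                                                  const$subject_ids),
                             cov, keep_full = TRUE)
  expect_true(is.na(r1$p[1, 1]))
  few <- make_geno(matrix(c(0L, 1L, 2L, 0L, 1L), 5, 1))  # df = 0
  r2 <- snp_voxel_regression(few, gmv_image_set(matrix(abs(rnorm(5)), 5, 1),
                                                c(1L, 1L, 1L), 1.5,
                                                few$subject_ids),
                             cov[1:5, ], keep_full = TRUE)
  expect_true(is.na(r2$p[1, 1]))
})

test_that("per-SNP complete cases are used when calls are missing", {
  set.seed(6)
  n <- 40L
  g <- as.integer(rbinom(n, 2, 0.4))
  calls <- matrix(g, n, 1)
  calls[1:5, 1] <- NA_integer_
  age <- runif(n, 16, 45); sex <- rbinom(n, 1, 0.5); edu <- runif(n, 6, 18)
  y <- 2 + 0.3 * g + 0.1 * sex + rnorm(n, sd = 0.4)
  geno <- make_geno(calls)
  cov <- data.frame(subject = geno$subject_ids, age = age, sex = sex,
                    education = edu, is_case = 1L)
  res <- snp_voxel_regression(geno, gmv_image_set(matrix(y, n, 1),
                                                  c(1L, 1L, 1L), 1.5,
                                                  geno$subject_ids),
                              cov, keep_full = TRUE)
  keep <- 6:40
  ora <- oracle_ols(y[keep], g[keep], age[keep], sex[keep], edu[keep])
  expect_equal(unname(res$beta[1, 1]), unname(ora$beta), tolerance = 1e-8)
  expect_equal(unname(res$p[1, 1]), unname(ora$p), tolerance = 1e-8)
})

test_that("type-I error is nominal under the null", {
  cfg <- sim_config(n_cases = 40L, n_controls = 40L, n_genes = 20L,
                    snps_per_gene = 2L, grid_shape = c(5L, 5L, 4L),
                    effect_plan = default_effect_plan()[0, ],
                    expr_module_plan = list(), subgroup_plan = NULL,
                    seed = 71L)
  st <- simulate_study(cfg)
  res <- snp_voxel_regression(st$genotypes, st$gmv, st$covariates,
                              keep_full = TRUE)
  pv <- as.vector(res$p)
  pv <- pv[!is.na(pv)]
  n_tests <- length(pv)
  for (alpha in c(0.05, 0.001)) {
    hit <- mean(pv < alpha)
    se <- sqrt(alpha * (1 - alpha) / n_tests)
    expect_lt(abs(hit - alpha), 4 * se + 1e-9)
  }
})

test_that("candidate selection respects the strict 1e-6 boundary", {
  res <- structure(list(
    pairs = data.frame(snp = c("s01", "s02"), voxel = c(1L, 2L),
                       i = 1L, j = 1L, k = 1:2,
                       beta = 1, t = 10, p = c(5e-7, 1e-6)),
    snp_min_p = c(s01 = 5e-7, s02 = 1e-6, s03 = 0.2),
    gene_min_p = c(G01 = 5e-7, G02 = 1e-6, G03 = 0.2),
    snp_meta = data.frame(id = c("s01", "s02", "s03"),
                          gene = c("G01", "G02", "G03"),
                          chrom = 1L, pos = 1:3,
                          stringsAsFactors = FALSE),
    grid_shape = c(2L, 2L, 2L), n_tests = 24, p_keep = 1e-4,
    n_subjects = 50), class = "association_result")
  out <- select_candidates(res, 1e-6)
  expect_identical(out$candidate_genes, "G01")
  expect_identical(out$significant_pairs$snp, "s01")
  expect_error(select_candidates(res, 1e-3), "p_keep")
})
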