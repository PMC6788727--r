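#' Simulate LD-blocked additive genotypes
#'
#' Draws a subjects x SNPs matrix of minor-allele counts in \{0, 1, 2\}.
#' Within each gene's SNP block, correlation is induced by a latent-Gaussian
#' threshold copula: subjects receive an exchangeably correlated latent
#' vector (correlation `ld_block_rho`), each coordinate of which is cut at
#' the Hardy–Weinberg genotype frequencies of that SNP's minor allele
#' frequency. Across genes, blocks are independent. Genes are assigned
#' round-robin to chromosomes 1–22.
#'
#' @param config a [sim_config()]
#' @return an object of class `genotype_matrix`: list with `calls`
#'   (subjects x SNPs integer matrix, `NA` = missing), `snp_meta`
#'   (data.frame: id, gene, chrom, pos, maf) and `subject_ids`
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(stage_seed(config$seed, 1L), {
    n <- config$n_cases + config$n_controls
    g <- config$n_genes; s <- config$snps_per_gene
    genes <- gene_symbols(g)
    # SNPs of one LD block share a base allele frequency (plus small
    # jitter), as variants on a common haplotype background do; without
    # this, MAF mismatch would erode within-block genotype correlation
    base_maf <- runif(g, config$maf_range[1], config$maf_range[2])
    mafs <- pmin(pmax(rep(base_maf, each = s) + runif(g * s, -0.02, 0.02),
                      config$maf_range[1]), config$maf_range[2])
    calls <- matrix(NA_integer_, n, g * s)
    rho <- config$ld_block_rho
    for (k in seq_len(g)) {
      f <- rnorm(n)
      z <- sqrt(rho) * f + sqrt(1 - rho) * matrix(rnorm(n * s), n, s)
      cols <- (k - 1L) * s + seq_len(s)
      for (j in seq_len(s)) {
        p <- mafs[cols[j]]
        q0 <- qnorm((1 - p)^2)            # below: homozygous major
        q1 <- qnorm((1 - p)^2 + 2 * p * (1 - p))
        calls[, cols[j]] <- (z[, j] > q0) + (z[, j] > q1)
      }
    }
    storage.mode(calls) <- "integer"
    if (config$missing_rate > 0) {
      miss <- runif(length(calls)) < config$missing_rate
      calls[miss] <- NA_integer_
    }
    snp_meta <- data.frame(
      id = sprintf("snp%05d", seq_len(g * s)),
      gene = rep(genes, each = s),
      chrom = rep(((seq_len(g) - 1L) %% 22L) + 1L, each = s),
      pos = rep((seq_len(g) - 1L) * 100000L, each = s) +
        rep(seq_len(s), g) * 1000L,
      maf = mafs,
      stringsAsFactors = FALSE)
    subject_ids <- c(sprintf("case%03d", seq_len(config$n_cases)),
                     sprintf("ctrl%03d", seq_len(config$n_controls)))
    dimnames(calls) <- list(subject_ids, snp_meta$id)
    genotype_matrix(calls, snp_meta, subject_ids)
  })
}

#' Construct a genotype_matrix object
#'
#' @param calls subjects x SNPs matrix with values in \{0, 1, 2, NA\}
#' @param snp_meta data.frame with one row per SNP: `id`, `gene`, `chrom`,
#'   `pos` (every SNP maps to exactly one gene symbol)
#' @param subject_ids ordered subject identifiers
#' @return `genotype_matrix` object
#' @export
genotype_matrix <- function(calls, snp_meta, subject_ids = rownames(calls)) {
  ok <- calls %in% c(0L, 1L, 2L, NA)
  if (!all(ok)) stop("genotype calls must be 0, 1, 2 or missing")
  if (nrow(snp_meta) != ncol(calls)) stop("snp_meta/calls mismatch")
  if (anyDuplicated(snp_meta$id)) stop("duplicated SNP ids")
  structure(list(calls = calls, snp_meta = snp_meta,
                 subject_ids = subject_ids),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$calls), "subjects x", ncol(x$calls),
      "SNPs (", length(unique(x$snp_meta$gene)), "genes );",
      sum(is.na(x$calls)), "missing calls\n")
  invisible(x)
}

#' Simulate the covariate table
#'
#' Age ~ Uniform(16, 45) years, sex coded 0/1 with equal probability,
#' education ~ Uniform(6, 18) years; cases and controls are drawn from the
#' same distributions (a matched design). `is_case` flags diagnostic status.
#'
#' @param config a [sim_config()]
#' @return data.frame: subject, age, sex, education, is_case
#' @export
simulate_covariates <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(stage_seed(config$seed, 2L), {
    n <- config$n_cases + config$n_controls
    data.frame(
      subject = c(sprintf("case%03d", seq_len(config$n_cases)),
                  sprintf("ctrl%03d", seq_len(config$n_controls))),
      age = round(runif(n, 16, 45), 1),
      sex = rbinom(n, 1L, 0.5),
      education = round(runif(n, 6, 18), 1),
      is_case = rep(c(1L, 0L), c(config$n_cases, config$n_controls)),
      stringsAsFactors = FALSE)
  })
}
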