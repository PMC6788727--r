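#' Remove subjects with a low genotyping rate
#'
#' Subjects whose per-subject call rate falls strictly below
#' `min_call_rate` (default 97%) are dropped; survivor order is preserved.
#'
#' @param g a `genotype_matrix`
#' @param min_call_rate minimum fraction of non-missing calls to retain
#' @return filtered `genotype_matrix`
#' @export
qc_subjects <- function(g, min_call_rate = 0.97) {
  stopifnot(inherits(g, "genotype_matrix"))
  rate <- rowMeans(!is.na(g$calls))
  keep <- rate >= min_call_rate
  if (!any(keep)) stop("all subjects removed by call-rate QC")
  genotype_matrix(g$calls[keep, , drop = FALSE], g$snp_meta,
                  g$subject_ids[keep])
}

#' Marker-level genotype QC
#'
#' Excludes markers with more than `max_missing` missing calls, minor
#' allele frequency less than or equal to `min_maf` (computed over all
#' retained subjects, cases and controls pooled), or a Hardy–Weinberg
#' equilibrium test p-value less than or equal to `hwe_alpha`.
#'
#' @param g a `genotype_matrix`
#' @param max_missing maximum tolerated missing fraction (strictly more
#'   is removed)
#' @param min_maf MAF at or below this is removed
#' @param hwe_alpha HWE p at or below this is removed
#' @param hwe_method "exact" (enumeration over heterozygote counts) or
#'   "chisq" (1-df goodness of fit)
#' @return filtered `genotype_matrix`
#' @export
qc_markers <- function(g, max_missing = 0.05, min_maf = 0.05,
                       hwe_alpha = 1e-6, hwe_method = c("exact", "chisq")) {
  stopifnot(inherits(g, "genotype_matrix"), nrow(g$calls) >= 1)
  hwe_method <- match.arg(hwe_method)
  calls <- g$calls
  missfrac <- colMeans(is.na(calls))
  n0 <- colSums(calls == 0L, na.rm = TRUE)
  n1 <- colSums(calls == 1L, na.rm = TRUE)
  n2 <- colSums(calls == 2L, na.rm = TRUE)
  maf <- snp_maf(calls)
  hwe_p <- vapply(seq_len(ncol(calls)), function(j) {
    if (hwe_method == "exact") hwe_exact_p(n0[j], n1[j], n2[j])
    else hwe_chisq_p(n0[j], n1[j], n2[j])
  }, numeric(1))
  keep <- missfrac <= max_missing & maf > min_maf & hwe_p > hwe_alpha
  if (!any(keep)) stop("no markers survive QC")
  genotype_matrix(calls[, keep, drop = FALSE],
                  g$snp_meta[keep, , drop = FALSE], g$subject_ids)
}

#' Minor allele frequency per SNP
#'
#' Frequency of the allele counted by the 0/1/2 coding, folded so that the
#' reported value is always the minor (<= 0.5) frequency.
#'
#' @param calls subjects x SNPs matrix in \{0,1,2,NA\}
#' @return numeric vector of MAFs
#' @export
snp_maf <- function(calls) {
  f <- colMeans(calls, na.rm = TRUE) / 2
  pmin(f, 1 - f)
}

#' Exact Hardy–Weinberg equilibrium test
#'
#' Conditional on the observed minor-allele count, enumerates the
#' probability of every possible heterozygote count and sums those with
#' probability not exceeding that of the observed configuration
#' (the standard exact SNP-HWE construction).
#'
#' @param n_aa,n_ab,n_bb genotype counts (major hom, het, minor hom)
#' @return two-sided exact p-value
#' @export
hwe_exact_p <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  if (n == 0) return(1)
  n_minor <- 2 * n_bb + n_ab           # folded below if needed
  if (n_minor > n) {                   # ensure "minor" really is minor
    tmp <- n_aa; n_aa <- n_bb; n_bb <- tmp
    n_minor <- 2 * n_bb + n_ab
  }
  hets <- seq(n_minor %% 2, min(n_minor, 2 * n - n_minor), by = 2)
  # log P(n_ab = h | n, n_minor) up to a constant
  lp <- vapply(hets, function(h) {
    hom_min <- (n_minor - h) / 2
    hom_maj <- n - h - hom_min
    h * log(2) - lfactorial(hom_maj) - lfactorial(h) - lfactorial(hom_min)
  }, numeric(1))
  pr <- exp(lp - max(lp)); pr <- pr / sum(pr)
  obs <- pr[match(n_ab, hets)]
  min(1, sum(pr[pr <= obs * (1 + 1e-12)]))
}

#' Chi-squared Hardy–Weinberg test (1 df)
#' @inheritParams hwe_exact_p
#' @return p-value from the chi-squared approximation
#' @export
hwe_chisq_p <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  if (n == 0) return(1)
  p <- (2 * n_bb + n_ab) / (2 * n)
  e <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
  if (any(e == 0)) return(1)
  x2 <- sum((c(n_aa, n_ab, n_bb) - e)^2 / e)
  stats::pchisq(x2, df = 1, lower.tail = FALSE)
}

#' Voxel-wise SNP association screen on grey-matter volume
#'
#' For every SNP `s` and in-mask voxel `v`, fits the ordinary
#' least-squares model
#' `GMV_v = b0 + b1 * g_s + b2 * age + b3 * sex + b4 * education + e`
#' over subjects with a non-missing call at `s`, and reports the genotype
#' slope `b1`, its t statistic and the two-sided p-value on
#' `n_used - 5` degrees of freedom. A SNP with a constant genotype (or too
#' few subjects) yields missing statistics for all its voxels.
#'
#' To keep memory bounded at realistic voxel counts, per-pair statistics
#' are retained only for pairs with `p < p_keep`; per-SNP and per-gene
#' minimum p-values are always retained. Set `keep_full = TRUE` on small
#' problems to keep the full beta/t/p matrices.
#'
#' @param g post-QC `genotype_matrix`
#' @param gmv a `gmv_image_set` over the same subjects, same order
#' @param cov covariate data.frame (`subject`, `age`, `sex`, `education`)
#' @param voxel_mask logical 3D array of voxels to test (default: all)
#' @param p_keep retain per-pair records below this p
#' @param keep_full retain full SNP x voxel beta/t/p matrices
#' @return `association_result`: list with `pairs` (data.frame snp, voxel,
#'   i, j, k, beta, t, p for retained pairs), `snp_min_p`, `gene_min_p`,
#'   `n_tests`, plus `beta`/`t`/`p` matrices when `keep_full`
#' @export
snp_voxel_regression <- function(g, gmv, cov, voxel_mask = NULL,
                                 p_keep = 1e-4, keep_full = FALSE) {
  stopifnot(inherits(g, "genotype_matrix"), inherits(gmv, "gmv_image_set"))
  if (!identical(g$subject_ids, gmv$subject_ids) ||
      !identical(g$subject_ids, cov$subject))
    stop("subjects must align across genotypes, GMV and covariates")
  dimg <- gmv$grid_shape
  if (is.null(voxel_mask)) voxel_mask <- array(TRUE, dim = dimg)
  if (!identical(dim(voxel_mask), dimg)) stop("voxel_mask grid mismatch")
  vox <- which(voxel_mask)
  Y <- gmv$data[, vox, drop = FALSE]
  n <- nrow(Y); nv <- length(vox); ns <- ncol(g$calls)
  X0 <- cbind(1, cov$age, cov$sex, cov$education)

  snp_min_p <- rep(NA_real_, ns)
  pair_list <- vector("list", ns)
  if (keep_full) {
    BM <- matrix(NA_real_, ns, nv); TM <- BM; PM <- BM
  }
  complete <- !is.na(g$calls)
  all_complete <- all(complete)

  for (s in seq_len(ns)) {
    gs <- g$calls[, s]
    if (all_complete) { use <- TRUE; gv <- as.numeric(gs); Xs <- X0; Ys <- Y }
    else {
      use <- complete[, s]
      gv <- as.numeric(gs[use]); Xs <- X0[use, , drop = FALSE]
      Ys <- Y[use, , drop = FALSE]
    }
    nu <- length(gv); df <- nu - 5L
    if (df <= 0 || stats::var(gv) == 0) next
    X <- cbind(Xs, gv)
    XtX <- crossprod(X)
    XtXi <- tryCatch(solve(XtX), error = function(e) NULL)
    if (is.null(XtXi)) next
    B <- XtXi %*% crossprod(X, Ys)          # 5 x nv coefficients
    res <- Ys - X %*% B
    rss <- colSums(res^2)
    se <- sqrt(pmax(rss, 0) / df * XtXi[5, 5])
    beta1 <- B[5, ]
    tstat <- ifelse(se > 0, beta1 / se, NA_real_)
    pv <- 2 * stats::pt(-abs(tstat), df = df)
    snp_min_p[s] <- suppressWarnings(min(pv, na.rm = TRUE))
    hit <- which(!is.na(pv) & pv < p_keep)
    if (length(hit) > 0) {
      ijk <- vox_ijk(vox[hit], dimg)
      pair_list[[s]] <- data.frame(
        snp = g$snp_meta$id[s], voxel = vox[hit],
        i = ijk[, 1], j = ijk[, 2], k = ijk[, 3],
        beta = beta1[hit], t = tstat[hit], p = pv[hit],
        stringsAsFactors = FALSE)
    }
    if (keep_full) { BM[s, ] <- beta1; TM[s, ] <- tstat; PM[s, ] <- pv }
  }
  snp_min_p[!is.finite(snp_min_p)] <- NA_real_
  pairs <- do.call(rbind, pair_list[!vapply(pair_list, is.null, logical(1))])
  if (is.null(pairs))
    pairs <- data.frame(snp = character(0), voxel = integer(0),
                        i = integer(0), j = integer(0), k = integer(0),
                        beta = numeric(0), t = numeric(0), p = numeric(0))
  gene_min_p <- tapply(snp_min_p, g$snp_meta$gene, function(x)
    suppressWarnings(min(x, na.rm = TRUE)))
  gene_min_p[!is.finite(gene_min_p)] <- NA_real_
  res <- list(pairs = pairs, snp_min_p = stats::setNames(snp_min_p,
                                                         g$snp_meta$id),
              gene_min_p = gene_min_p,
              snp_meta = g$snp_meta, grid_shape = dimg,
              n_tests = sum(!is.na(snp_min_p)) * nv, p_keep = p_keep,
              n_subjects = n)
  if (keep_full) {
    dimnames(BM) <- list(g$snp_meta$id, NULL)
    res$beta <- BM; res$t <- TM; res$p <- PM; res$voxels <- vox
  }
  class(res) <- "association_result"
  res
}

#' @export
print.association_result <- function(x, ...) {
  cat("association_result:", length(x$snp_min_p), "SNPs,", x$n_tests,
      "tests;", nrow(x$pairs), "pairs kept below p <", x$p_keep, "\n")
  if (!is.null(x$candidate_genes))
    cat("  candidates (p <", x$p_threshold, "):",
        length(x$candidate_genes), "genes,",
        nrow(x$significant_pairs), "significant pairs\n")
  invisible(x)
}

#' Select candidate genes and significant SNP-voxel pairs
#'
#' A gene is a candidate when at least one of its SNPs reaches a p-value
#' strictly below `p_threshold` at some voxel (default 1e-6); significant
#' pairs are all retained pairs below the same threshold.
#'
#' @param res an `association_result`
#' @param p_threshold strict significance cut
#' @return the `association_result` with `candidate_genes`,
#'   `significant_pairs`, `p_threshold` and a per-gene summary table
#'   (`gene_summary`: gene, best SNP, min p, number of significant voxels)
#' @export
select_candidates <- function(res, p_threshold = 1e-6) {
  stopifnot(inherits(res, "association_result"))
  if (p_threshold > res$p_keep)
    stop("p_threshold exceeds p_keep used at regression time; ",
         "re-run snp_voxel_regression with a larger p_keep")
  sig <- res$pairs[res$pairs$p < p_threshold, , drop = FALSE]
  gmp <- res$gene_min_p
  cand <- names(gmp)[!is.na(gmp) & gmp < p_threshold]
  best_snp <- vapply(names(gmp), function(gn) {
    sid <- res$snp_meta$id[res$snp_meta$gene == gn]
    mp <- res$snp_min_p[sid]
    if (all(is.na(mp))) NA_character_ else sid[which.min(mp)]
  }, character(1))
  nsig <- vapply(names(gmp), function(gn) {
    sid <- res$snp_meta$id[res$snp_meta$gene == gn]
    length(unique(sig$voxel[sig$snp %in% sid]))
  }, integer(1))
  res$significant_pairs <- sig
  res$candidate_genes <- cand
  res$p_threshold <- p_threshold
  res$gene_summary <- data.frame(
    gene = names(gmp), best_snp = best_snp, min_p = as.numeric(gmp),
    n_sig_voxels = nsig, candidate = names(gmp) %in% cand,
    row.names = NULL, stringsAsFactors = FALSE)
  res$gene_summary <- res$gene_summary[order(res$gene_summary$min_p), ]
  res
}
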