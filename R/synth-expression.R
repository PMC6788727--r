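#' Construct an expression set
#'
#' @param matrix genes x samples numeric matrix with gene ids as rownames
#' @param sample_meta data.frame with per-sample `sample`, `region`
#'   (FC/SC/SM/TP), `stage` (1/2/3) and optional `age` descriptor
#' @return `expression_set` object
#' @export
expression_set <- function(matrix, sample_meta) {
  stopifnot(ncol(matrix) == nrow(sample_meta))
  if (anyDuplicated(rownames(matrix))) stop("gene ids must be unique")
  if (!all(sample_meta$region %in% c("FC", "SC", "SM", "TP")))
    stop("region labels must be FC, SC, SM or TP")
  if (!all(sample_meta$stage %in% 1:3)) stop("stage labels must be 1, 2 or 3")
  structure(list(matrix = matrix, sample_meta = sample_meta),
            class = "expression_set")
}

#' @export
print.expression_set <- function(x, ...) {
  cat("expression_set:", nrow(x$matrix), "genes x", ncol(x$matrix),
      "samples over",
      nrow(unique(x$sample_meta[, c("region", "stage")])), "strata\n")
  invisible(x)
}

#' Simulate spatio-temporal expression with planted co-expressed modules
#'
#' Generates one expression stratum per (region, stage) combination —
#' four brain regions (FC, SC, SM, TP) by three developmental stages —
#' with `expr_samples_per_stratum` samples each. Background genes are
#' independent standard normal everywhere. Genes of a planted module are
#' drawn from a one-factor model inside their stratum, giving every pair
#' the stated within-module correlation `rho`; outside that stratum they
#' behave as background.
#'
#' @param config a [sim_config()]
#' @return an `expression_set`
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  genes <- gene_symbols(config$n_genes)
  for (m in config$expr_module_plan)
    if (!all(m$genes %in% genes))
      stop("module gene not in gene universe: ",
           paste(setdiff(m$genes, genes), collapse = ", "))
  regions <- c("FC", "SC", "SM", "TP"); stages <- 1:3
  ns <- config$expr_samples_per_stratum
  stage_ages <- c("8-37 pcw", "4 mo-8 yr", "13-40 yr")

  with_seed(stage_seed(config$seed, 4L), {
    mats <- list(); metas <- list(); k <- 0L
    for (rg in regions) for (st in stages) {
      k <- k + 1L
      x <- matrix(rnorm(config$n_genes * ns), config$n_genes, ns,
                  dimnames = list(genes, NULL))
      for (m in config$expr_module_plan) {
        if (m$region == rg && m$stage == st) {
          f <- rnorm(ns)
          gi <- match(m$genes, genes)
          x[gi, ] <- sqrt(m$rho) * matrix(f, length(gi), ns, byrow = TRUE) +
            sqrt(1 - m$rho) * matrix(rnorm(length(gi) * ns), length(gi), ns)
        }
      }
      mats[[k]] <- x
      metas[[k]] <- data.frame(
        sample = sprintf("%s_s%d_%02d", rg, st, seq_len(ns)),
        region = rg, stage = st, age = stage_ages[st],
        stringsAsFactors = FALSE)
    }
    mat <- do.call(cbind, mats)
    meta <- do.call(rbind, metas)
    colnames(mat) <- meta$sample
    expression_set(mat, meta)
  })
}
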