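#' Build a thresholded co-expression network for one stratum
#'
#' Computes the absolute Pearson correlation of every gene pair over the
#' samples of one (region, stage) stratum — or over all samples pooled
#' when `stratum = "merged"` — and keeps an edge only where |PCC| strictly
#' exceeds `threshold`. In weighted mode the surviving edge carries its
#' |PCC|; in unweighted mode it is binarised to 1. Genes with zero
#' variance in the stratum keep their node but get no edges (warning).
#'
#' @param expr an `expression_set`
#' @param stratum `c(region, stage)`, e.g. `c("FC", 2)`, or `"merged"`
#' @param threshold edge threshold on |PCC| (strict >)
#' @param weighted keep |PCC| weights (`TRUE`) or binarise (`FALSE`)
#' @return `coexpression_network`: list with `genes`, `weights`
#'   (symmetric, zero diagonal), `threshold`, `weighted`, `stratum`
#' @export
build_network <- function(expr, stratum, threshold = 0.8, weighted = TRUE) {
  stopifnot(inherits(expr, "expression_set"))
  if (identical(stratum, "merged") || identical(stratum, c("merged"))) {
    cols <- seq_len(ncol(expr$matrix)); sid <- "merged"
  } else {
    rg <- as.character(stratum[1]); st <- as.integer(stratum[2])
    cols <- which(expr$sample_meta$region == rg & expr$sample_meta$stage == st)
    sid <- paste0(rg, "_", st)
  }
  if (length(cols) < 3) stop("stratum has fewer than 3 samples")
  x <- expr$matrix[, cols, drop = FALSE]
  sds <- apply(x, 1, stats::sd)
  if (any(sds == 0))
    warning(sum(sds == 0), " zero-variance gene(s) in stratum ", sid,
            "; their correlations set to 0", call. = FALSE)
  w <- abs(suppressWarnings(stats::cor(t(x))))
  w[!is.finite(w)] <- 0
  w[w <= threshold] <- 0
  if (!weighted) w <- (w > 0) * 1
  diag(w) <- 0
  structure(list(genes = rownames(expr$matrix), weights = w,
                 threshold = threshold, weighted = weighted, stratum = sid),
            class = "coexpression_network")
}

#' @export
print.coexpression_network <- function(x, ...) {
  cat("coexpression_network [", x$stratum, "]:", length(x$genes), "genes,",
      sum(x$weights > 0) / 2, "edges (|PCC| >", x$threshold,
      if (x$weighted) ", weighted" else ", unweighted", ")\n")
  invisible(x)
}

#' Interconnectedness of a gene set
#'
#' The sum of the (thresholded) edge weights among the genes of the set,
#' each unordered pair counted once.
#'
#' @param net a `coexpression_network`
#' @param genes character vector of gene ids within the network universe
#' @return non-negative scalar
#' @export
interconnectedness <- function(net, genes) {
  stopifnot(inherits(net, "coexpression_network"))
  idx <- match(genes, net$genes)
  if (anyNA(idx))
    stop("unknown gene id(s): ",
         paste(genes[is.na(idx)], collapse = ", "))
  if (length(idx) < 2) return(0)
  sum(net$weights[idx, idx]) / 2
}

#' Resampling test of candidate-gene interconnectedness
#'
#' Compares the observed interconnectedness of the candidate set against
#' an empirical null built by repeatedly drawing equally sized gene sets
#' uniformly (without replacement within a draw) from the pool. The
#' p-value is the fraction of null draws at least as large as the
#' observed value, with the add-one finite-sample correction
#' `p = (#\{null >= obs\} + 1) / (n + 1)` by default.
#'
#' @param net a `coexpression_network`
#' @param candidates candidate gene set
#' @param pool resampling pool (candidates must be a subset)
#' @param n_resamples number of null draws
#' @param seed integer seed
#' @param add_one apply the add-one correction (otherwise the raw
#'   fraction, which can be exactly 0)
#' @param ties count null values equal to the observed one as extreme
#'   (`TRUE`, conservative) or require strict exceedance (`FALSE`)
#' @return `interconnectedness_result`: observed, null_samples, p_value,
#'   n_resamples, stratum
#' @export
resampling_test <- function(net, candidates, pool, n_resamples = 10000,
                            seed = 1L, add_one = TRUE, ties = TRUE) {
  stopifnot(inherits(net, "coexpression_network"))
  if (!all(candidates %in% pool)) stop("candidates must be a subset of pool")
  pidx <- match(pool, net$genes)
  if (anyNA(pidx)) stop("pool gene(s) missing from network universe")
  k <- length(candidates)
  if (k > length(pool)) stop("more candidates than pool genes")
  obs <- interconnectedness(net, candidates)
  W <- net$weights
  nulls <- with_seed(seed, {
    vapply(seq_len(n_resamples), function(r) {
      s <- pidx[sample.int(length(pidx), k)]
      sum(W[s, s]) / 2
    }, numeric(1))
  })
  extreme <- if (ties) sum(nulls >= obs) else sum(nulls > obs)
  p <- if (add_one) (extreme + 1) / (n_resamples + 1)
       else extreme / n_resamples
  structure(list(observed = obs, null_samples = nulls, p_value = p,
                 n_resamples = n_resamples, stratum = net$stratum,
                 n_candidates = k),
            class = "interconnectedness_result")
}

#' @export
print.interconnectedness_result <- function(x, ...) {
  star <- if (x$p_value < 0.01) " ***" else if (x$p_value < 0.1) " *" else ""
  cat(sprintf(
    "interconnectedness [%s]: observed %.3f (%d genes), p = %.4g over %d resamples%s\n",
    x$stratum, x$observed, x$n_candidates, x$p_value, x$n_resamples, star))
  invisible(x)
}

#' Stability suite over strata, thresholds and weighting modes
#'
#' Runs the resampling test in every (region, stage) stratum plus the
#' merged network, for each requested |PCC| threshold and for weighted and
#' unweighted edges, mirroring the robustness table of the original
#' analysis.
#'
#' @param expr an `expression_set`
#' @param candidates candidate gene set
#' @param pool resampling pool
#' @param thresholds numeric vector of |PCC| thresholds
#' @param weighted_modes logical vector of weighting modes to test
#' @param n_resamples null draws per cell
#' @param seed integer seed (one sub-seed per cell)
#' @return data.frame: stratum, region, stage, threshold, weighted,
#'   observed, p_value
#' @export
stability_suite <- function(expr, candidates, pool, thresholds = 0.8,
                            weighted_modes = c(TRUE, FALSE),
                            n_resamples = 10000, seed = 1L) {
  strata <- c(lapply(seq_len(12), function(i) {
    c(c("FC", "SC", "SM", "TP")[(i - 1) %/% 3 + 1], ((i - 1) %% 3) + 1)
  }), list("merged"))
  rows <- list(); cell <- 0L
  for (st in strata) for (th in thresholds) for (wm in weighted_modes) {
    cell <- cell + 1L
    net <- build_network(expr, st, threshold = th, weighted = wm)
    r <- resampling_test(net, candidates, pool, n_resamples,
                         seed = stage_seed(seed, cell))
    rows[[cell]] <- data.frame(
      stratum = net$stratum,
      region = if (identical(st, "merged")) NA_character_ else st[1],
      stage = if (identical(st, "merged")) NA_integer_ else as.integer(st[2]),
      threshold = th, weighted = wm,
      observed = r$observed, p_value = r$p_value,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
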