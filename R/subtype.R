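#' Mean GMV features over hot clusters
#'
#' @param gmv a `gmv_image_set`
#' @param clusters list of `hot_cluster` on the same grid
#' @param subjects optional subject ids/rows to restrict to (e.g. the
#'   patients with PANSS records)
#' @return patients x HCs numeric matrix (rows named by subject, columns
#'   by cluster id)
#' @export
extract_hc_features <- function(gmv, clusters, subjects = NULL) {
  stopifnot(inherits(gmv, "gmv_image_set"), length(clusters) > 0)
  for (cl in clusters) {
    if (cl$size == 0) stop("empty cluster: ", cl$id)
    if (!is.null(cl$grid_shape) &&
        !identical(as.integer(cl$grid_shape), gmv$grid_shape))
      stop("clusters and GMV are on different grids")
  }
  rows <- if (is.null(subjects)) seq_len(nrow(gmv$data)) else subjects
  feat <- vapply(clusters, function(cl)
    rowMeans(gmv$data[rows, cl$voxels, drop = FALSE]),
    numeric(length(if (is.character(rows)) rows else rows)))
  feat <- matrix(feat, ncol = length(clusters))
  rownames(feat) <- if (is.character(rows)) rows else gmv$subject_ids[rows]
  colnames(feat) <- vapply(clusters, `[[`, character(1), "id")
  feat
}

#' Row-standardize a feature matrix (zero mean, unit norm per row)
#' @keywords internal
row_standardize <- function(x) {
  xc <- sweep(x, 1, rowMeans(x))
  nr <- sqrt(rowSums(xc^2))
  if (any(nr == 0)) {
    bad <- rownames(x)[nr == 0] %||% which(nr == 0)
    stop("constant feature row(s): ", paste(bad, collapse = ", "),
         " (correlation distance undefined)")
  }
  xc / nr
}

#' Correlation distance between feature rows and centroid rows
#' @keywords internal
cor_dist <- function(x, centers) {
  d <- 1 - suppressWarnings(stats::cor(t(x), t(centers)))
  d[is.na(d)] <- 1     # degenerate (constant) centroid: uncorrelated
  d
}

#' K-means under the correlation distance
#'
#' Lloyd iterations with distance `d(x, y) = 1 - PCC(x, y)`: points are
#' assigned to the centroid at minimal correlation distance and centroids
#' are recomputed as the mean of their members' row-standardized features.
#' `n_replicates` random initialisations (centroids seeded from K distinct
#' data points) are run and the solution with the minimal sum of
#' within-group point-to-centroid distances is kept.
#'
#' @param feat patients x features matrix with non-constant rows
#' @param K number of groups
#' @param n_replicates random restarts
#' @param seed integer seed
#' @param max_iter Lloyd iteration cap per replicate
#' @return list: `labels` (1..K per patient), `cost` (best within-group
#'   distance sum), `K`, `centers`
#' @export
correlation_kmeans <- function(feat, K, n_replicates = 1000, seed = 1L,
                               max_iter = 100) {
  stopifnot(nrow(feat) >= K, K >= 1)
  xs <- row_standardize(feat)
  n <- nrow(xs)
  with_seed(seed, {
    best <- NULL
    for (rep in seq_len(n_replicates)) {
      centers <- xs[sample.int(n, K), , drop = FALSE]
      labels <- integer(n)
      for (it in seq_len(max_iter)) {
        d <- cor_dist(xs, centers)
        new_labels <- max.col(-d, ties.method = "first")
        # re-seed empty groups from the point farthest from its centroid;
        # capped: with fewer distinct profiles than K some groups can
        # never be filled (e.g. two-feature data has only two distinct
        # standardized rows), and they are then left empty
        for (attempt in seq_len(K)) {
          empty <- setdiff(seq_len(K), unique(new_labels))
          if (length(empty) == 0) break
          far <- which.max(d[cbind(seq_len(n), new_labels)])
          centers[empty[1], ] <- xs[far, ]
          d[, empty[1]] <- cor_dist(xs, centers[empty[1], , drop = FALSE])
          new_labels <- max.col(-d, ties.method = "first")
        }
        if (identical(new_labels, labels)) break
        labels <- new_labels
        for (k in seq_len(K))
          centers[k, ] <- colMeans(xs[labels == k, , drop = FALSE])
      }
      cost <- sum(cor_dist(xs, centers)[cbind(seq_len(n), labels)])
      if (is.null(best) || cost < best$cost)
        best <- list(labels = labels, cost = cost, K = K, centers = centers)
    }
    best
  })
}

#' In-group proportion of a clustering
#'
#' For each patient, the nearest other patient under the correlation
#' distance; a group's IGP is the fraction of its members whose nearest
#' neighbour shares their label, and the mean IGP is the unweighted mean
#' over groups. Nearest-neighbour ties break to the lowest patient index.
#'
#' @param feat patients x features matrix
#' @param labels integer group labels
#' @return list: `igp_by_group` (named by group), `mean_igp`, `nn` index
#' @export
igp <- function(feat, labels) {
  stopifnot(nrow(feat) >= 2, length(labels) == nrow(feat))
  xs <- row_standardize(feat)
  d <- cor_dist(xs, xs)
  diag(d) <- Inf
  nn <- apply(d, 1, which.min)          # ties: lowest index
  same <- labels[nn] == labels
  igp_by_group <- vapply(split(same, labels), mean, numeric(1))
  list(igp_by_group = igp_by_group,
       mean_igp = mean(igp_by_group), nn = nn)
}

#' Choose the number of patient groups by mean IGP
#'
#' Runs [correlation_kmeans()] for each K in `k_range` and keeps the K
#' with maximal mean in-group proportion (ties resolved to the smallest
#' K). Each K draws its own sub-seed from `seed`, so adding values to
#' `k_range` never changes the other fits.
#'
#' @param feat patients x features matrix
#' @param k_range candidate group counts (default 2:10)
#' @param n_replicates K-means restarts per K
#' @param seed integer seed
#' @return `subtype_result`: `labels`, `K`, `igp_by_k`, `igp_by_group`,
#'   `within_group_cost`, `n_replicates`, `seed`, `fits`
#' @export
choose_k <- function(feat, k_range = 2:10, n_replicates = 1000, seed = 1L) {
  stopifnot(max(k_range) <= nrow(feat))
  fits <- list(); igps <- stats::setNames(numeric(length(k_range)),
                                          as.character(k_range))
  for (i in seq_along(k_range)) {
    K <- k_range[i]
    fit <- correlation_kmeans(feat, K, n_replicates,
                              seed = stage_seed(seed, K))
    fit$igp <- igp(feat, fit$labels)
    fits[[as.character(K)]] <- fit
    igps[i] <- fit$igp$mean_igp
  }
  bestK <- k_range[which.max(igps)]     # which.max: first max = smallest K
  best <- fits[[as.character(bestK)]]
  structure(list(labels = best$labels, K = bestK, igp_by_k = igps,
                 igp_by_group = best$igp$igp_by_group,
                 within_group_cost = best$cost,
                 n_replicates = n_replicates, seed = seed, fits = fits),
            class = "subtype_result")
}

#' @export
print.subtype_result <- function(x, ...) {
  cat("subtype_result: K =", x$K, "( mean IGP",
      round(x$igp_by_k[as.character(x$K)], 3), "); group sizes:",
      paste(table(x$labels), collapse = "/"), "\n")
  invisible(x)
}

#' PANSS subscale scores
#'
#' Computes the positive (P, 7 items), negative (N, 7 items) and general
#' psychopathology (G, 16 items) subscales, the total TT = P + N + G and
#' the composite PN = P - N from 30 item scores, validating that every
#' item lies in the instrument's 1–7 range. If subscale columns are
#' already present they are checked against the recomputed sums and a
#' mismatch is an error.
#'
#' @param items data.frame containing columns P1..P7, N1..N7, G1..G16
#' @return the input with columns P, N, G, TT, PN appended/validated
#' @export
panss_subscales <- function(items) {
  nm <- panss_item_names()
  if (!all(nm %in% names(items))) stop("missing PANSS item columns")
  m <- as.matrix(items[, nm])
  if (any(m < 1 | m > 7)) stop("PANSS items must lie in [1, 7]")
  P <- rowSums(m[, 1:7, drop = FALSE])
  N <- rowSums(m[, 8:14, drop = FALSE])
  G <- rowSums(m[, 15:30, drop = FALSE])
  derived <- list(P = P, N = N, G = G, TT = P + N + G, PN = P - N)
  for (s in names(derived)) {
    if (s %in% names(items) && any(items[[s]] != derived[[s]]))
      stop("recorded subscale ", s, " disagrees with item sums")
    items[[s]] <- derived[[s]]
  }
  items
}

#' Permutation tests of PANSS subscales across patient groups
#'
#' For each subscale (P, N, G, TT, PN) builds a null distribution by
#' permuting group labels `n_perm` times with group sizes fixed, and
#' reports (i) each group's observed mean with its two-tailed permutation
#' p-value, (ii) each pairwise difference of group means with its
#' two-tailed p-value, and (iii) an omnibus statistic (the largest
#' absolute pairwise difference). Two-tailed p doubles the smaller tail
#' (add-one corrected) and is capped at 1; `tails = "one"` gives the
#' upper-tail test.
#'
#' @param panss data.frame with subscales (see [panss_subscales()]; they
#'   are computed if absent)
#' @param labels integer group labels, one per patient
#' @param n_perm number of permutations
#' @param seed integer seed
#' @param tails "two" (default) or "one"
#' @return list: `group_means` (subscale, group, mean, p), `pairwise`
#'   (subscale, g1, g2, diff, p), `omnibus` (subscale, stat, p), `nulls`
#'   (list of null sample matrices for plotting)
#' @export
permutation_test_subscales <- function(panss, labels, n_perm = 10000,
                                       seed = 1L, tails = c("two", "one")) {
  tails <- match.arg(tails)
  if (!all(c("P", "N", "G", "TT", "PN") %in% names(panss)))
    panss <- panss_subscales(panss)
  stopifnot(length(labels) == nrow(panss))
  if (!is.null(panss$patient)) {
    # canonical patient order, so the permutation stream (and hence every
    # p-value) is invariant to how the input rows happen to be arranged
    ord <- order(panss$patient)
    panss <- panss[ord, , drop = FALSE]
    labels <- labels[ord]
  }
  groups <- sort(unique(labels))
  G <- length(groups)
  sizes <- as.integer(table(factor(labels, levels = groups)))
  subs <- c("P", "N", "G", "TT", "PN")
  pairs <- if (G >= 2) utils::combn(groups, 2) else matrix(nrow = 2, ncol = 0)

  perm_idx <- with_seed(seed, {
    lapply(seq_len(n_perm), function(i) sample(labels))
  })
  two_tail_p <- function(nulls, obs) {
    lo <- sum(nulls <= obs); hi <- sum(nulls >= obs)
    if (tails == "one") return((hi + 1) / (length(nulls) + 1))
    min(1, 2 * (min(lo, hi) + 1) / (length(nulls) + 1))
  }

  gm_rows <- list(); pw_rows <- list(); om_rows <- list(); nulls <- list()
  for (s in subs) {
    x <- panss[[s]]
    fl <- factor(labels, levels = groups)
    obs_means <- tapply(x, fl, mean)
    null_means <- t(vapply(perm_idx, function(lab)
      tapply(x, factor(lab, levels = groups), mean), numeric(G)))
    gm_rows[[s]] <- data.frame(
      subscale = s, group = groups, mean = as.numeric(obs_means),
      p = vapply(seq_len(G), function(g)
        two_tail_p(null_means[, g], obs_means[g]), numeric(1)),
      stringsAsFactors = FALSE)
    if (ncol(pairs) > 0) {
      pw_rows[[s]] <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(q) {
        a <- match(pairs[1, q], groups); b <- match(pairs[2, q], groups)
        obs_d <- obs_means[a] - obs_means[b]
        null_d <- null_means[, a] - null_means[, b]
        data.frame(subscale = s, g1 = pairs[1, q], g2 = pairs[2, q],
                   diff = as.numeric(obs_d), p = two_tail_p(null_d, obs_d),
                   stringsAsFactors = FALSE)
      }))
      obs_om <- max(abs(outer(obs_means, obs_means, "-")))
      null_om <- apply(null_means, 1, function(mm)
        max(abs(outer(mm, mm, "-"))))
      om_rows[[s]] <- data.frame(
        subscale = s, stat = obs_om,
        p = (sum(null_om >= obs_om) + 1) / (n_perm + 1),
        stringsAsFactors = FALSE)
    }
    nulls[[s]] <- null_means
  }
  list(group_means = do.call(rbind, gm_rows),
       pairwise = do.call(rbind, pw_rows),
       omnibus = do.call(rbind, om_rows),
       nulls = nulls, n_perm = n_perm, groups = groups, sizes = sizes)
}

#' Rank-sum tests of HC-level GMV: each group versus the rest
#'
#' For every (group, HC) cell, a two-sided Wilcoxon rank-sum test of the
#' group's members against all remaining patients on that HC's mean GMV,
#' flagged at the Bonferroni-corrected level `alpha / n_HC`.
#'
#' @param feat patients x HCs feature matrix
#' @param labels integer group labels
#' @param alpha family-wise level before correction (default 0.05)
#' @return data.frame: group, hc, p, threshold, significant
#' @export
hc_group_gmv_test <- function(feat, labels, alpha = 0.05) {
  groups <- sort(unique(labels))
  if (length(groups) < 2) stop("need at least 2 groups")
  nhc <- ncol(feat)
  thr <- alpha / nhc
  rows <- list(); r <- 0L
  for (g in groups) {
    ing <- labels == g
    if (sum(ing) < 2) {
      warning("group ", g, " has fewer than 2 members; tests skipped",
              call. = FALSE)
      next
    }
    for (h in seq_len(nhc)) {
      r <- r + 1L
      p <- suppressWarnings(stats::wilcox.test(
        feat[ing, h], feat[!ing, h], alternative = "two.sided"))$p.value
      rows[[r]] <- data.frame(
        group = g, hc = colnames(feat)[h] %||% h, p = p,
        threshold = thr, significant = p < thr, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
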