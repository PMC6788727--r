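# Independent oracles used across the suite. Each reimplements the target
# quantity by the most direct route available (explicit normal equations,
# full enumeration, BFS flood fill), sharing no code with the package paths
# it checks.

# OLS via explicit (X'X)^-1 X'y, t statistic and two-sided p
oracle_ols <- function(y, g, age, sex, edu) {
  X <- cbind(1, age, sex, edu, g)
  XtXi <- solve(t(X) %*% X)
  b <- XtXi %*% t(X) %*% y
  res <- y - X %*% b
  df <- length(y) - ncol(X)
  s2 <- sum(res^2) / df
  se <- sqrt(s2 * XtXi[5, 5])
  tval <- b[5] / se
  list(beta = b[5], t = tval, p = 2 * pt(-abs(tval), df))
}

# exact HWE p by direct enumeration with log-factorial probabilities
oracle_hwe <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  nb <- 2 * n_bb + n_ab
  if (nb > n) { tmp <- n_aa; n_aa <- n_bb; n_bb <- tmp; nb <- 2 * n_bb + n_ab }
  hets <- seq(nb %% 2, min(nb, 2 * n - nb), by = 2)
  logp <- sapply(hets, function(h) {
    lfactorial(n) - lfactorial((nb - h) / 2) - lfactorial(h) -
      lfactorial(n - (nb + h) / 2) + h * log(2) +
      lfactorial(nb) + lfactorial(2 * n - nb) - lfactorial(2 * n)
  })
  pr <- exp(logp)
  obs <- pr[match(n_ab, hets)]
  min(1, sum(pr[pr <= obs * (1 + 1e-12)]))
}

# BFS flood fill connected components over supra-threshold voxels
oracle_flood_fill <- function(arr, threshold, connectivity) {
  d <- dim(arr)
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nz <- rowSums(abs(off))
  off <- switch(as.character(connectivity),
                "6" = off[nz == 1, , drop = FALSE],
                "18" = off[nz >= 1 & nz <= 2, , drop = FALSE],
                "26" = off[nz >= 1, , drop = FALSE])
  sup <- which(arr > threshold)
  seen <- logical(length(arr))
  comps <- list()
  for (s in sup) {
    if (seen[s]) next
    queue <- s; seen[s] <- TRUE; comp <- integer(0)
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      comp <- c(comp, v)
      ijk <- arrayInd(v, d)
      for (o in seq_len(nrow(off))) {
        n_ijk <- ijk + off[o, ]
        if (any(n_ijk < 1) || any(n_ijk > d)) next
        nl <- (n_ijk[3] - 1) * d[1] * d[2] + (n_ijk[2] - 1) * d[1] + n_ijk[1]
        if (!seen[nl] && arr[nl] > threshold) {
          seen[nl] <- TRUE
          queue <- c(queue, nl)
        }
      }
    }
    comps[[length(comps) + 1]] <- sort(comp)
  }
  comps
}

# exhaustive interconnectedness null over all size-k subsets of a pool
oracle_exhaustive_resampling <- function(W, genes, pool_idx, k, obs) {
  subsets <- combn(pool_idx, k)
  nulls <- apply(subsets, 2, function(s) sum(W[s, s]) / 2)
  mean(nulls >= obs)
}

# exact two-sided rank-sum p by enumeration of all group assignments
oracle_rank_sum <- function(x, y) {
  pooled <- c(x, y)
  r <- rank(pooled)
  obs_w <- sum(r[seq_along(x)])
  sets <- combn(length(pooled), length(x))
  ws <- apply(sets, 2, function(s) sum(r[s]))
  mu <- mean(ws)
  min(1, 2 * min(mean(ws <= obs_w), mean(ws >= obs_w)))
}

dice <- function(a_idx, b_idx) {
  2 * length(intersect(a_idx, b_idx)) / (length(a_idx) + length(b_idx))
}

# best label agreement over all permutations of 3 group labels
agreement3 <- function(labels, truth) {
  per <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
               c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  tab <- table(factor(labels, 1:3), factor(truth, 1:3))
  max(apply(per, 1, function(p) sum(tab[cbind(p, 1:3)]))) / length(truth)
}

# small complete study used by several module tests
tiny_config <- function(seed = 101L, ...) {
  sim_config(
    n_cases = 24L, n_controls = 24L, n_genes = 10L, snps_per_gene = 3L,
    effect_plan = data.frame(gene = "GENE001", snp = 2L, cx = 8, cy = 8,
                             cz = 8, radius = 2, beta = 1,
                             stringsAsFactors = FALSE),
    grid_shape = c(16L, 16L, 16L),
    expr_module_plan = list(),
    subgroup_plan = NULL,
    seed = seed, ...)
}
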