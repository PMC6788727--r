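#' Evaluate an expression under a fixed RNG seed, restoring RNG state
#'
#' All stochastic operations in the package funnel through this helper so
#' that a function's `seed` argument fully determines its output without
#' disturbing the caller's RNG stream.
#'
#' @param seed integer seed
#' @param expr expression to evaluate
#' @return the value of `expr`
#' @export
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
             sample.kind = "Rejection")
  }
  force(expr)
}

#' Derive a per-stage sub-seed from a global seed
#'
#' Counter-based derivation: stage `k` of a run seeded with `seed` always
#' receives the same sub-seed, so re-running one stage never shifts the
#' randomness of any other. Result is kept inside the 32-bit integer range.
#'
#' @param seed global integer seed
#' @param k stage counter (1, 2, ...)
#' @return integer sub-seed
#' @export
stage_seed <- function(seed, k) {
  s <- (abs(as.double(seed)) %% 2097143) * 1009 + as.double(k) * 7919
  as.integer(s %% 2147483647L) + 1L
}

#' Convert voxel (i, j, k) triples to linear indices
#' @keywords internal
vox_linear <- function(ijk, dim) {
  ijk <- matrix(as.integer(ijk), ncol = 3)
  stopifnot(all(ijk >= 1), all(t(ijk) <= dim))
  (ijk[, 3] - 1L) * dim[1] * dim[2] + (ijk[, 2] - 1L) * dim[1] + ijk[, 1]
}

#' Convert linear voxel indices to (i, j, k) triples
#' @keywords internal
vox_ijk <- function(idx, dim) {
  arrayInd(as.integer(idx), .dim = dim)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' FWHM of a Gaussian kernel to its standard deviation, in voxels
#'
#' FWHM = 2 * sqrt(2 * ln 2) * sigma; dividing by the voxel size converts
#' millimetres to voxel units.
#'
#' @param fwhm_mm kernel full-width at half-maximum, mm
#' @param voxel_size_mm isotropic voxel edge length, mm
#' @return sigma in voxel units
#' @export
fwhm_to_sigma <- function(fwhm_mm, voxel_size_mm) {
  stopifnot(fwhm_mm > 0, voxel_size_mm > 0)
  fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_size_mm
}
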