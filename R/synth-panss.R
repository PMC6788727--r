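#' PANSS item column names
#' @return character vector P1..P7, N1..N7, G1..G16
#' @export
panss_item_names <- function() {
  c(paste0("P", 1:7), paste0("N", 1:7), paste0("G", 1:16))
}

#' Simulate 30-item PANSS records with planted subgroup shifts
#'
#' Each item is generated as base 1 plus rounded half-normal noise
#' (scale `panss_noise_sd`), plus the patient's subgroup shift on the
#' positive and/or negative item blocks, clipped to the instrument's
#' 1–7 range. A warning is raised if a shift drives an entire item block
#' to the ceiling.
#'
#' @param config a [sim_config()]
#' @param truth `ground_truth` from [simulate_gmv()] (carries the group
#'   label of every case)
#' @return data.frame: patient id, 30 item columns (P1..G16), group
#' @export
simulate_panss <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "ground_truth"))
  group <- truth$true_group_labels
  if (length(group) != config$n_cases)
    stop("truth must carry a group label for every case")
  sp <- config$subgroup_plan
  with_seed(stage_seed(config$seed, 5L), {
    n <- config$n_cases
    items <- matrix(1 + round(abs(rnorm(n * 30, sd = config$panss_noise_sd))),
                    n, 30, dimnames = list(NULL, panss_item_names()))
    if (!is.null(sp)) {
      items[, 1:7] <- items[, 1:7] + sp$panss_p_shift[group]
      items[, 8:14] <- items[, 8:14] + sp$panss_n_shift[group]
    }
    clipped_hi <- items > 7
    items[items < 1] <- 1; items[clipped_hi] <- 7
    for (blk in list(P = 1:7, N = 8:14)) {
      if (any(rowSums(items[, blk, drop = FALSE] == 7) == length(blk)))
        warning("a planted shift drove a full item block to the ceiling",
                call. = FALSE)
    }
    storage.mode(items) <- "integer"
    data.frame(patient = sprintf("case%03d", seq_len(n)), items,
               group = group, stringsAsFactors = FALSE)
  })
}
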