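#' Simulate a complete synthetic study
#'
#' Runs every generator under sub-seeds derived from `config$seed` and
#' returns all pipeline inputs plus the planted ground truth.
#'
#' @param config a [sim_config()]
#' @return list: `config`, `genotypes`, `covariates`, `gmv`, `truth`,
#'   `expression`, `panss`, `atlas`
#' @export
simulate_study <- function(config = sim_config()) {
  genotypes <- simulate_genotypes(config)
  covariates <- simulate_covariates(config)
  gt <- simulate_gmv(config, genotypes, covariates)
  expr <- simulate_expression(config)
  panss <- simulate_panss(config, gt$truth)
  atlas <- simulate_atlas(config)
  list(config = config, genotypes = genotypes, covariates = covariates,
       gmv = gt$gmv, truth = gt$truth, expression = expr, panss = panss,
       atlas = atlas)
}
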