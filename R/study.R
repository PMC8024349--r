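#' Simulate a complete synthetic study
#'
#' Runs every generator in order -- pedigree, dosages, planted QTL,
#' test-day phenotypes, gene models + genome, expression atlas, PWMs --
#' and returns them with the completed ground truth. All randomness
#' derives from `config$seed`.
#'
#' @param config a [sim_config()].
#' @param annotation include gene models/genome (slowest part; default
#'   TRUE).
#' @return list of class `milkqtl_study` with `config`, `pedigree`,
#'   `dosages`, `test_days`, `annotation`, `atlas`, `pwms`, `truth`.
#' @export
simulate_study <- function(config, annotation = TRUE) {
  config <- validate_sim_config(config)
  ped <- simulate_pedigree(config)
  dos <- simulate_dosages(config, ped)
  truth <- plant_qtl(config, dos)
  td <- simulate_test_days(config, ped, dos, truth)
  truth <- attr(td, "truth")
  ann <- if (annotation) simulate_annotation(config) else NULL
  atlas <- simulate_expression_atlas(config, truth)
  truth <- attr(atlas, "truth") %||% truth
  pwms <- simulate_pwms(config)
  structure(list(config = config, pedigree = ped, dosages = dos,
                 test_days = td, annotation = ann, atlas = atlas,
                 pwms = pwms, truth = truth),
            class = "milkqtl_study")
}
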