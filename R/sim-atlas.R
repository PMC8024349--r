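#' Simulate a multi-tissue expression atlas
#'
#' Emulates a gene-expression atlas of scaled log2 FPKM values: tissues
#' grouped into biological categories, several samples per tissue, and
#' sample-level covariates (age, sex, study). Each gene has a baseline
#' mean; designated genes receive a `overexpression_shift` residual-SD
#' mean shift in one target tissue (two genes per tissue by default),
#' recorded as the ground-truth overexpressed-gene map.
#'
#' @param config a [sim_config()].
#' @param truth optional `ground_truth` whose `overexpressed_gene_map`
#'   slot is filled (a fresh list is returned as an attribute otherwise).
#' @return list of class `expression_atlas`: `expr` (genes x samples
#'   matrix, rownames GENExxx), `samples` (data.frame: `sample`, `tissue`,
#'   `category`, `age`, `sex`, `study`), and
#'   `overexpressed_gene_map` (tissue -> gene ids).
#' @export
simulate_expression_atlas <- function(config, truth = NULL) {
  config <- validate_sim_config(config)
  set.seed(sim_subseed(config$seed, 6L))
  nt <- config$n_tissues; nc <- config$n_categories
  ns <- config$samples_per_tissue
  if (nt < 2L * nc) stop("each category needs >= 2 tissues")
  tissues <- c("mammary gland", "white blood cells", "liver", "kidney",
               "rumen", "muscle", "adipose", "ovary", "lung", "spleen",
               "jejunum", "hypothalamus")
  tissues <- if (nt <= length(tissues)) tissues[seq_len(nt)]
             else c(tissues, sprintf("tissue%02d", seq_len(nt - length(tissues))))
  category <- rep_len(seq_len(nc), nt)[order(rep_len(seq_len(nc), nt))]
  category <- sprintf("cat%d", rep_len(seq_len(nc), nt))
  n_samp <- nt * ns
  samples <- data.frame(
    sample = sprintf("S%03d", seq_len(n_samp)),
    tissue = rep(tissues, each = ns),
    category = rep(category, each = ns),
    age = stats::runif(n_samp, 0.5, 8),
    sex = sample(c("F", "M"), n_samp, replace = TRUE),
    study = sample(sprintf("study%d", 1:4), n_samp, replace = TRUE),
    stringsAsFactors = FALSE)
  genes <- sprintf("GENE%03d", seq_len(config$n_genes))
  base <- stats::rnorm(config$n_genes, 0, 1.5)
  expr <- matrix(stats::rnorm(config$n_genes * n_samp, 0, 1),
                 config$n_genes, n_samp,
                 dimnames = list(genes, samples$sample)) + base
  # small covariate effects so the model has something to adjust for
  age_eff <- stats::rnorm(config$n_genes, 0, 0.05)
  expr <- expr + outer(age_eff, samples$age)
  expr <- expr + outer(stats::rnorm(config$n_genes, 0, 0.1),
                       as.numeric(samples$sex == "M"))
  # plant overexpressed genes: 2 per tissue, cycling through genes
  oe_map <- list()
  if (config$n_genes < 2L * nt)
    warning("fewer genes than 2 per tissue; overexpressed genes recycle ",
            "across tissues and planted shifts partly cancel")
  gi <- 1L
  for (tt in tissues) {
    picks <- genes[((gi - 1L):(gi)) %% config$n_genes + 1L]
    gi <- gi + 2L
    oe_map[[tt]] <- picks
    cols <- samples$tissue == tt
    expr[picks, cols] <- expr[picks, cols] + config$overexpression_shift
  }
  out <- list(expr = expr, samples = samples, overexpressed_gene_map = oe_map)
  if (!is.null(truth)) {
    truth$overexpressed_gene_map <- oe_map
    attr(out, "truth") <- truth
  }
  class(out) <- "expression_atlas"
  out
}
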