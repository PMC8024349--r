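#' Simulation configuration for the synthetic study generator
#'
#' Bundles every knob of the synthetic-data generator that emulates a
#' test-day dairy study: a multi-generation pedigree of cows nested within
#' sires, LD-structured biallelic allele dosages with a chip/imputed
#' distinction, repeated test-day phenotypes with herd x test-day, lactation
#' stage, season and permanent-environment effects, planted QTL of known
#' effect, gene models with non-coding biotypes, transcription-factor PWMs,
#' and a multi-tissue expression atlas.
#'
#' Defaults describe a desk-scale analogue of a large commercial test-day
#' design: six milk mineral/citrate-like traits with heritabilities between
#' 0.3 and 0.6 and genetic correlations between -0.25 and 0.60, at least
#' seven records per cow, and imputed dosages with mean imputation R2 near
#' 0.67 and a chip subset fixed at R2 = 1.
#'
#' @param seed integer seed; every generator consumes it deterministically.
#' @param n_cows number of phenotyped cows (non-founder females).
#' @param n_sires number of sires; must be < `n_cows`.
#' @param n_generations number of female generations below the founders.
#' @param n_traits number of traits.
#' @param h2_targets per-trait heritability targets in (0,1).
#' @param rg_matrix symmetric PSD genetic-correlation matrix, unit diagonal.
#' @param pe_frac per-trait permanent-environment fraction of phenotypic
#'   variance (repeatability minus heritability).
#' @param n_variants total biallelic variants across chromosomes.
#' @param n_chromosomes number of autosomes.
#' @param chrom_len chromosome length in base pairs.
#' @param ld_block_len LD block length in base pairs; variants within a
#'   block are near-copies of a founder block haplotype.
#' @param flip_rate per-haplotype allele flip probability used to decay LD
#'   within a block.
#' @param chip_frac fraction of variants flagged as chip (imputation R2 = 1).
#' @param n_qtl number of planted causal variants.
#' @param qtl_effect_sd SD of planted allele-substitution effects, in trait
#'   units (used when `qtl_var_frac` is NULL).
#' @param qtl_var_frac optional fraction of additive variance each planted
#'   QTL should explain; overrides `qtl_effect_sd`.
#' @param records_per_cow integer range (min, max) of test-day records.
#' @param n_herds number of herds.
#' @param var_htd variance of herd x test-day effects (trait units squared).
#' @param n_tissues number of atlas tissues.
#' @param n_categories number of biological categories grouping the tissues.
#' @param samples_per_tissue samples per tissue (>= 2).
#' @param n_genes number of genes in the synthetic annotation/atlas.
#' @param overexpression_shift mean shift (in residual SDs) given to the
#'   designated overexpressed gene in its target tissue.
#' @param n_pwms number of simulated PWMs.
#' @param gene_drop logical; when TRUE dosages are inherited through the
#'   pedigree by Mendelian gene dropping, otherwise individuals draw
#'   independent block genotypes.
#'
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed = 1L,
                       n_cows = 1000L,
                       n_sires = 50L,
                       n_generations = 3L,
                       n_traits = 6L,
                       h2_targets = c(0.57, 0.45, 0.38, 0.33, 0.47, 0.42),
                       rg_matrix = default_rg_matrix(n_traits),
                       pe_frac = rep(0.15, n_traits),
                       n_variants = 2000L,
                       n_chromosomes = 2L,
                       chrom_len = 20e6,
                       ld_block_len = 100e3,
                       flip_rate = 0.01,
                       chip_frac = 0.10,
                       n_qtl = 5L,
                       qtl_effect_sd = 0.25,
                       qtl_var_frac = NULL,
                       records_per_cow = c(7L, 11L),
                       n_herds = 20L,
                       var_htd = 0.2,
                       n_tissues = 12L,
                       n_categories = 4L,
                       samples_per_tissue = 6L,
                       n_genes = 60L,
                       overexpression_shift = 3,
                       n_pwms = 8L,
                       gene_drop = TRUE) {
  h2_targets <- rep_len(h2_targets, n_traits)
  pe_frac <- rep_len(pe_frac, n_traits)
  cfg <- list(seed = as.integer(seed), n_cows = as.integer(n_cows),
              n_sires = as.integer(n_sires),
              n_generations = as.integer(n_generations),
              n_traits = as.integer(n_traits), h2_targets = h2_targets,
              rg_matrix = rg_matrix, pe_frac = pe_frac,
              n_variants = as.integer(n_variants),
              n_chromosomes = as.integer(n_chromosomes),
              chrom_len = chrom_len, ld_block_len = ld_block_len,
              flip_rate = flip_rate, chip_frac = chip_frac,
              n_qtl = as.integer(n_qtl), qtl_effect_sd = qtl_effect_sd,
              qtl_var_frac = qtl_var_frac,
              records_per_cow = as.integer(records_per_cow),
              n_herds = as.integer(n_herds), var_htd = var_htd,
              n_tissues = as.integer(n_tissues),
              n_categories = as.integer(n_categories),
              samples_per_tissue = as.integer(samples_per_tissue),
              n_genes = as.integer(n_genes),
              overexpression_shift = overexpression_shift,
              n_pwms = as.integer(n_pwms), gene_drop = isTRUE(gene_drop))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

#' @keywords internal
validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_sires < 1L) stop("n_sires must be >= 1")
  if (cfg$n_cows < 2L) stop("n_cows must be >= 2")
  if (cfg$n_sires >= cfg$n_cows) stop("n_sires must be < n_cows")
  if (any(cfg$h2_targets <= 0 | cfg$h2_targets >= 1))
    stop("h2_targets must all lie in (0, 1)")
  if (any(cfg$pe_frac < 0) || any(cfg$h2_targets + cfg$pe_frac >= 1))
    stop("pe_frac must be >= 0 with h2 + pe < 1")
  rg <- cfg$rg_matrix
  if (!is.matrix(rg) || nrow(rg) != cfg$n_traits || ncol(rg) != cfg$n_traits)
    stop("rg_matrix must be n_traits x n_traits")
  if (max(abs(rg - t(rg))) > 1e-8) stop("rg_matrix must be symmetric")
  if (max(abs(diag(rg) - 1)) > 1e-8) stop("rg_matrix must have unit diagonal")
  ev <- eigen(rg, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) stop("rg_matrix must be positive semi-definite")
  if (cfg$n_variants < cfg$n_qtl) stop("n_variants must be >= n_qtl")
  if (length(cfg$records_per_cow) != 2L ||
      cfg$records_per_cow[1] > cfg$records_per_cow[2] ||
      cfg$records_per_cow[1] < 1L)
    stop("records_per_cow must be a valid (min, max) range")
  if (cfg$samples_per_tissue < 2L)
    stop("samples_per_tissue must be >= 2 (t-statistic undefined otherwise)")
  if (cfg$n_tissues < 2L * cfg$n_categories)
    stop("need at least 2 tissues per category")
  cfg
}

#' Default genetic-correlation matrix
#'
#' A fixed symmetric PSD correlation matrix with pairwise values spanning
#' roughly -0.25 to 0.60, the scale typical of milk mineral traits.
#'
#' @param n_traits number of traits (<= 6 uses the canonical block, larger
#'   values pad with near-zero correlations).
#' @return an `n_traits` x `n_traits` correlation matrix.
#' @export
default_rg_matrix <- function(n_traits = 6L) {
  base <- matrix(c(
    1.00,  0.60,  0.35,  0.10, -0.10, 0.20,
    0.60,  1.00,  0.45,  0.15, -0.20, 0.25,
    0.35,  0.45,  1.00,  0.30, -0.05, 0.15,
    0.10,  0.15,  0.30,  1.00, -0.25, 0.10,
   -0.10, -0.20, -0.05, -0.25,  1.00, 0.05,
    0.20,  0.25,  0.15,  0.10,  0.05, 1.00), 6L, 6L)
  if (n_traits <= 6L) return(base[seq_len(n_traits), seq_len(n_traits), drop = FALSE])
  out <- diag(n_traits)
  out[1:6, 1:6] <- base
  out
}

#' True variance components implied by a configuration
#'
#' Phenotypic variance is fixed at 1 per trait; additive variance equals the
#' heritability target, permanent-environment variance the `pe_frac` target,
#' and the residual takes the remainder. Additive covariances follow the
#' genetic-correlation matrix; permanent-environment and residual
#' correlations are fixed mild positive values (0.3 and 0.1).
#'
#' @param config a [sim_config()].
#' @return list with matrices `G0`, `P0`, `R0` (n_traits square).
#' @export
true_varcomps <- function(config) {
  h2 <- config$h2_targets
  pe <- config$pe_frac
  re <- 1 - h2 - pe
  G0 <- config$rg_matrix * sqrt(outer(h2, h2))
  cor_pe <- matrix(0.3, config$n_traits, config$n_traits); diag(cor_pe) <- 1
  cor_re <- matrix(0.1, config$n_traits, config$n_traits); diag(cor_re) <- 1
  P0 <- cor_pe * sqrt(outer(pe, pe))
  R0 <- cor_re * sqrt(outer(re, re))
  list(G0 = G0, P0 = P0, R0 = R0)
}

# Derive a reproducible sub-seed so each simulate_* consumes an independent
# stream while staying a function of config$seed alone (kept below 2^31).
sim_subseed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset * 9973) %% 2147483647)
}
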