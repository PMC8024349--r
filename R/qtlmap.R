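#' Bonferroni genome-wide significance threshold
#'
#' Returns -log10(alpha / n_tests). With 12,907,802 tests and alpha = 0.05
#' this is 8.41 (displayed as 8.4), i.e. a nominal per-test P of 4e-9.
#'
#' @param n_tests number of (assumed independent) tests.
#' @param alpha genome-wide type-I error rate.
#' @return the threshold on the -log10(P) scale (full precision; round to
#'   1 decimal for display).
#' @export
genome_wide_threshold <- function(n_tests, alpha = 0.05) {
  stopifnot(n_tests >= 1, alpha > 0, alpha < 1)
  log10(n_tests) - log10(alpha)
}

#' Cluster significant variants into QTL regions
#'
#' Per chromosome and trait, significant variants (mlog10p >= threshold)
#' are chained by single linkage: two consecutive significant variants
#' belong to the same region when their gap is strictly less than
#' `max_gap` base pairs (default 2 Mbp). Singleton regions are allowed.
#'
#' @param results a `gwas_result`.
#' @param threshold genome-wide -log10(P) threshold.
#' @param max_gap maximum within-region gap in bp (strict "less than").
#' @return data.frame of class `qtl_regions`, one row per region: `region`,
#'   `trait`, `chrom`, `from`, `to` (member span), `n_variants`, `top_id`,
#'   `top_pos`, `top_mlog10p`, `top_b`, `top_se`, `top_freq`, `top_r2`,
#'   plus `members` (list column of variant ids). CI columns `ci_from`,
#'   `ci_to` are filled by [confidence_interval()].
#' @export
cluster_qtl <- function(results, threshold, max_gap = 2e6) {
  sig <- results[!is.na(results$mlog10p) & results$mlog10p >= threshold, ,
                 drop = FALSE]
  out <- list()
  if (nrow(sig)) {
    sig <- sig[order(sig$chrom, sig$pos), , drop = FALSE]
    for (ch in unique(sig$chrom)) {
      s <- sig[sig$chrom == ch, , drop = FALSE]
      grp <- cumsum(c(1, diff(s$pos) >= max_gap))
      for (g in unique(grp)) {
        m <- s[grp == g, , drop = FALSE]
        top <- top_variant_rank(m)[1L]
        out[[length(out) + 1L]] <- data.frame(
          trait = attr(results, "trait") %||% NA_character_,
          chrom = ch, from = min(m$pos), to = max(m$pos),
          ci_from = NA_real_, ci_to = NA_real_,
          n_variants = nrow(m),
          top_id = m$id[top], top_pos = m$pos[top],
          top_mlog10p = m$mlog10p[top], top_b = m$b[top],
          top_se = m$se[top], top_freq = m$freq[top], top_r2 = m$r2[top],
          stringsAsFactors = FALSE)
        out[[length(out)]]$members <- I(list(m$id))
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out)
         else data.frame(trait = character(0), chrom = integer(0),
                         from = numeric(0), to = numeric(0),
                         ci_from = numeric(0), ci_to = numeric(0),
                         n_variants = integer(0), top_id = character(0),
                         top_pos = numeric(0), top_mlog10p = numeric(0),
                         top_b = numeric(0), top_se = numeric(0),
                         top_freq = numeric(0), top_r2 = numeric(0),
                         members = I(list()))
  if (nrow(res)) res$region <- seq_len(nrow(res))
  attr(res, "threshold") <- threshold
  class(res) <- c("qtl_regions", "data.frame")
  res
}

# ranking order within a set of variants: highest -log10P, then higher
# imputation R2, then lower position
top_variant_rank <- function(m) {
  order(-m$mlog10p, -m$r2, m$pos)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Confidence interval from the upper third of the QTL peak
#'
#' Let M be the region's maximum -log10(P) and T the significance
#' threshold. The CI spans the positions of member variants whose score
#' reaches the upper third of the peak. By default the peak is measured
#' from the threshold (`from = "threshold"`): the cut is
#' T + (2/3)(M - T). With `from = "zero"` the cut is (2/3)M. The top
#' variant is always included.
#'
#' @param regions a `qtl_regions` table.
#' @param results the `gwas_result` the regions came from.
#' @param from `"threshold"` (default) or `"zero"`.
#' @param cut_fraction fraction of the peak that defines the upper part
#'   (default 2/3, i.e. the upper third).
#' @return `regions` with `ci_from`/`ci_to` filled.
#' @export
confidence_interval <- function(regions, results, from = c("threshold", "zero"),
                                cut_fraction = 2 / 3) {
  from <- match.arg(from)
  thr <- attr(regions, "threshold")
  for (i in seq_len(nrow(regions))) {
    ids <- regions$members[[i]]
    m <- results[match(ids, results$id), , drop = FALSE]
    M <- max(m$mlog10p)
    cut <- if (from == "threshold") thr + cut_fraction * (M - thr)
           else cut_fraction * M
    keep <- m$mlog10p >= cut
    keep[which.max(m$mlog10p)] <- TRUE
    regions$ci_from[i] <- min(m$pos[keep])
    regions$ci_to[i] <- max(m$pos[keep])
  }
  regions
}

#' Conditional analysis of neighbouring QTL regions
#'
#' Re-runs the mixed-linear-model scan on one chromosome with the lead
#' variant's dosage included as a fixed covariate. Variants whose dosage
#' correlation with the lead satisfies r^2 >= `r2_max` are skipped. A
#' region is rejected when none of its tested member variants remains
#' significant at the genome-wide threshold after conditioning.
#'
#' @param regions `qtl_regions` on one chromosome (one trait).
#' @param yd yield deviations.
#' @param dosages `dosage_matrix` containing the member variants.
#' @param null the [fit_null()] result used for the original scan.
#' @param lead_id id of the conditioning variant (default: the top variant
#'   of the most significant region).
#' @param threshold genome-wide -log10(P) threshold (default: the one the
#'   regions were clustered at).
#' @param r2_max LD exclusion threshold against the lead (default 0.9).
#' @return `regions` with logical column `retained`, numeric
#'   `cond_max_mlog10p`, and `n_tested`; the lead's own region is always
#'   retained. `attr(x, "conditional_scan")` holds the per-variant
#'   conditional results.
#' @export
conditional_scan <- function(regions, yd, dosages, null, lead_id = NULL,
                             threshold = attr(regions, "threshold"),
                             r2_max = 0.9) {
  stopifnot(nrow(regions) >= 1L)
  if (is.null(lead_id))
    lead_id <- regions$top_id[which.max(regions$top_mlog10p)]
  if (!lead_id %in% colnames(dosages$dosage))
    stop("lead variant ", lead_id, " absent from dosages")
  xl <- dosages$dosage[null$ids, lead_id]
  if (stats::var(xl) == 0) stop("lead variant is monomorphic")
  member_ids <- unique(unlist(regions$members))
  r2_lead <- suppressWarnings(
    stats::cor(dosages$dosage[null$ids, member_ids, drop = FALSE], xl))^2
  test_ids <- member_ids[!is.na(r2_lead) & r2_lead < r2_max]
  sub <- dosages
  keep <- match(test_ids, colnames(dosages$dosage))
  sub$dosage <- dosages$dosage[, keep, drop = FALSE]
  sub$map <- dosages$map[keep, , drop = FALSE]
  cond <- if (length(test_ids))
    mlma_scan(yd, sub, null, covariates = cbind(lead = xl))
  else NULL
  regions$retained <- FALSE
  regions$cond_max_mlog10p <- NA_real_
  regions$n_tested <- 0L
  lead_region <- which(vapply(regions$members, function(m) lead_id %in% m,
                              TRUE))
  for (i in seq_len(nrow(regions))) {
    ids <- intersect(regions$members[[i]], test_ids)
    regions$n_tested[i] <- length(ids)
    if (length(ids) && !is.null(cond)) {
      mx <- max(cond$mlog10p[match(ids, cond$id)], na.rm = TRUE)
      regions$cond_max_mlog10p[i] <- mx
      regions$retained[i] <- mx >= threshold
    }
  }
  if (length(lead_region)) regions$retained[lead_region] <- TRUE
  attr(regions, "conditional_scan") <- cond
  attr(regions, "lead_id") <- lead_id
  regions
}

#' Percentage of additive genetic variance explained by a QTL
#'
#' 100 * 2 p (1-p) b^2 / sigma_g2 with p the ALT allele frequency, b the
#' allele-substitution effect and sigma_g2 the additive (genomic) variance
#' of the trait's yield deviations.
#'
#' @param p ALT allele frequency in (0,1).
#' @param b allele-substitution effect (trait units per ALT dose).
#' @param sigma_g2 additive genetic variance (> 0).
#' @return percentage (vectorized).
#' @export
variance_explained <- function(p, b, sigma_g2) {
  stopifnot(all(p > 0 & p < 1), all(sigma_g2 > 0))
  100 * 2 * p * (1 - p) * b^2 / sigma_g2
}

#' Detect QTL from a GWAS result (threshold, cluster, CI, variance)
#'
#' Convenience wrapper: applies [genome_wide_threshold()] (or a supplied
#' threshold), [cluster_qtl()], [confidence_interval()], and
#' [variance_explained()] using the null-model additive variance.
#'
#' @param results `gwas_result`.
#' @param n_tests number of tests for the Bonferroni threshold (default:
#'   number of non-NA results).
#' @param alpha genome-wide alpha.
#' @param max_gap clustering gap (bp).
#' @param sigma_g2 additive variance of the yield deviations (for
#'   `variance_explained`); NA skips the column.
#' @param ... passed to [confidence_interval()].
#' @return a `qtl_regions` table with CIs and `pct_var_explained`.
#' @export
detect_qtl <- function(results, n_tests = sum(!is.na(results$mlog10p)),
                       alpha = 0.05, max_gap = 2e6, sigma_g2 = NA_real_,
                       ...) {
  thr <- genome_wide_threshold(n_tests, alpha)
  reg <- cluster_qtl(results, thr, max_gap)
  if (nrow(reg)) {
    reg <- confidence_interval(reg, results, ...)
    reg$pct_var_explained <- if (is.finite(sigma_g2))
      variance_explained(reg$top_freq, reg$top_b, sigma_g2) else NA_real_
  }
  reg
}
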