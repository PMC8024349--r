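#' Scan a sequence with a PWM
#'
#' Slides the motif over every offset of the sequence on both strands and
#' returns the maximum log2-odds score. Ties are broken deterministically:
#' lowest offset first, then "+" strand before "-". Ambiguous bases (not
#' A/C/G/T) contribute 0 (the background log-odds) and are counted in
#' `n_ambiguous`.
#'
#' @param sequence character string (or DNAString) with length >= motif
#'   length.
#' @param pwm a [pwm()].
#' @return list: `score` (bits), `offset` (0-based window start on the
#'   forward sequence), `strand` ("+"/"-"), `n_ambiguous`.
#' @export
scan_pwm <- function(sequence, pwm) {
  s <- toupper(as.character(sequence))
  x <- strsplit(s, "")[[1L]]
  L <- pwm$length
  n <- length(x)
  if (n < L) stop("sequence shorter than motif")
  idx <- match(x, c("A", "C", "G", "T"))
  n_amb <- sum(is.na(idx))
  Sf <- pwm$score
  Sr <- Sf[4:1, L:1, drop = FALSE]      # reverse-complement score matrix
  n_off <- n - L + 1L
  score_f <- numeric(n_off); score_r <- numeric(n_off)
  for (j in seq_len(L)) {
    b <- idx[j:(j + n_off - 1L)]
    cf <- Sf[, j][b]; cr <- Sr[, j][b]
    cf[is.na(cf)] <- 0; cr[is.na(cr)] <- 0
    score_f <- score_f + cf
    score_r <- score_r + cr
  }
  allsc <- c(score_f, score_r)
  best <- max(allsc)
  # tie rule: lowest offset, then + strand
  cand_f <- which(score_f >= best - 1e-12)
  cand_r <- which(score_r >= best - 1e-12)
  off_f <- if (length(cand_f)) min(cand_f) else Inf
  off_r <- if (length(cand_r)) min(cand_r) else Inf
  if (off_f <= off_r)
    list(score = best, offset = off_f - 1L, strand = "+", n_ambiguous = n_amb)
  else
    list(score = best, offset = off_r - 1L, strand = "-", n_ambiguous = n_amb)
}

#' Null distribution of single-window PWM scores under background
#'
#' For motifs of length <= `exact_max` the distribution is computed
#' analytically by convolving the per-position score distributions
#' (equivalent to enumerating all 4^L windows, but collapsing duplicate
#' partial sums); longer motifs fall back to Monte Carlo sampling of
#' background windows.
#'
#' @param pwm a [pwm()].
#' @param exact_max maximum motif length for the exact path (default 12).
#' @param n_sample Monte Carlo sample size for long motifs.
#' @return function `p(score)` returning P(window score >= score) under
#'   the background model; `attr(.,"method")` is "exact" or "sample".
#' @export
pwm_null <- function(pwm, exact_max = 12L, n_sample = 1e5) {
  bg <- pwm$background
  if (pwm$length <= exact_max) {
    val <- 0; pr <- 1
    for (j in seq_len(pwm$length)) {
      v <- outer(val, pwm$score[, j], "+")
      p <- outer(pr, bg, "*")
      key <- round(as.numeric(v), 9)
      agg <- rowsum(as.numeric(p), key)
      val <- as.numeric(rownames(agg)); pr <- agg[, 1L]
      if (length(val) > 2e6) {  # degenerate blow-up guard: bin at 1e-6
        key <- round(val, 6)
        agg <- rowsum(pr, key)
        val <- as.numeric(rownames(agg)); pr <- agg[, 1L]
      }
    }
    o <- order(val)
    val <- val[o]; pr <- pr[o]
    tail_p <- rev(cumsum(rev(pr)))
    f <- function(score)
      ifelse(score <= val[1L], 1,
             ifelse(score > val[length(val)] + 1e-9, 0,
                    tail_p[pmax(1L, findInterval(score - 1e-9, val) + 1L)]))
    attr(f, "method") <- "exact"
  } else {
    idx <- matrix(sample.int(4L, n_sample * pwm$length, replace = TRUE,
                             prob = bg), n_sample, pwm$length)
    sc <- numeric(n_sample)
    for (j in seq_len(pwm$length)) sc <- sc + pwm$score[, j][idx[, j]]
    sc <- sort(sc)
    f <- function(score)
      vapply(score, function(s) mean(sc >= s - 1e-9), 1)
    attr(f, "method") <- "sample"
  }
  f
}

#' Call TFBS gains and losses at variants
#'
#' For each variant and each PWM: extract the window of motif length - 1
#' bases either side of the variant, score the reference and alternate
#' alleles ([scan_pwm()], both strands), convert both best scores to
#' empirical site P-values under the per-PWM background null
#' ([pwm_null()]), and call
#' `loss` when the reference site is significant (P < `p_site`) but the
#' alternate is not, `gain` for the reverse, `none` otherwise. Variants
#' too close to a contig edge are skipped and counted in
#' `attr(x, "skipped")`.
#'
#' @param variants data.frame with `chrom`, `pos`, `ref`, `alt` (SNVs).
#' @param genome a [Biostrings::DNAStringSet] (names = chromosomes).
#' @param lib a `pwm_library`.
#' @param p_site site-significance level (default 0.05).
#' @param nulls optional precomputed list of [pwm_null()] functions.
#' @return data.frame of class `rsnp_calls`: `id`, `chrom`, `pos`, `tf`,
#'   `strand`, `ref_score`, `alt_score`, `delta`, `offset` (best ref
#'   window start relative to the variant), `p_ref`, `p_alt`, `verdict`.
#' @export
tfbs_alteration <- function(variants, genome, lib, p_site = 0.05,
                            nulls = NULL) {
  if (is.null(variants$id))
    variants$id <- sprintf("%s:%d", variants$chrom, variants$pos)
  if (is.null(nulls)) nulls <- lapply(lib, pwm_null)
  out <- list(); skipped <- character(0)
  for (k in seq_len(nrow(variants))) {
    v <- variants[k, ]
    chrom <- as.character(v$chrom)
    clen <- Biostrings::width(genome[match(chrom, names(genome))])
    for (tf in names(lib)) {
      p <- lib[[tf]]
      flank <- p$length - 1L
      lo <- v$pos - flank; hi <- v$pos + flank
      if (lo < 1L || hi > clen) {
        skipped <- c(skipped, paste0(v$id, "/", tf)); next
      }
      refwin <- as.character(Biostrings::subseq(genome[[chrom]], lo, hi))
      if (substr(refwin, flank + 1L, flank + 1L) != v$ref)
        stop("REF mismatch at ", v$id)
      altwin <- refwin
      substr(altwin, flank + 1L, flank + 1L) <- v$alt
      sr <- scan_pwm(refwin, p)
      sa <- scan_pwm(altwin, p)
      pr <- nulls[[tf]](sr$score)
      pa <- nulls[[tf]](sa$score)
      verdict <- if (pr < p_site && pa >= p_site) "loss"
                 else if (pa < p_site && pr >= p_site) "gain"
                 else "none"
      out[[length(out) + 1L]] <- data.frame(
        id = v$id, chrom = chrom, pos = v$pos, tf = tf,
        strand = sr$strand, ref_score = sr$score, alt_score = sa$score,
        delta = sa$score - sr$score, offset = sr$offset - flank,
        p_ref = pr, p_alt = pa, verdict = verdict,
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out)
         else data.frame(id = character(0), chrom = character(0),
                         pos = numeric(0), tf = character(0),
                         strand = character(0), ref_score = numeric(0),
                         alt_score = numeric(0), delta = numeric(0),
                         offset = numeric(0), p_ref = numeric(0),
                         p_alt = numeric(0), verdict = character(0))
  attr(res, "skipped") <- skipped
  class(res) <- c("rsnp_calls", "data.frame")
  res
}

#' Tissue-specificity t-statistic for one gene and tissue
#'
#' Fits expression = mean + b_t x_t + covariates + error by ordinary least
#' squares on the samples of the tested tissue (coded x_t = +1) together
#' with the samples outside the tissue's biological category (coded -1);
#' same-category other-tissue samples are excluded. Covariates (age, sex,
#' study by default) that are collinear with the tissue indicator are
#' dropped with a warning. t = b_t / SE(b_t); Pt is two-sided from the
#' residual degrees of freedom.
#'
#' @param atlas an `expression_atlas`.
#' @param gene gene id (rowname of `atlas$expr`).
#' @param tissue tissue name.
#' @param covariates character vector of sample covariates to adjust for
#'   (subset of `c("age", "sex", "study")`); NULL for none.
#' @return one-row data.frame: `gene`, `tissue`, `b`, `t`, `pt`, `df`.
#' @export
tissue_t <- function(atlas, gene, tissue, covariates = c("age", "sex", "study")) {
  sm <- atlas$samples
  if (!tissue %in% sm$tissue) stop("unknown tissue: ", tissue)
  cat_t <- sm$category[match(tissue, sm$tissue)]
  in_t <- sm$tissue == tissue
  out_cat <- sm$category != cat_t
  if (sum(in_t) < 2L) stop("tissue has < 2 samples; t undefined")
  if (sum(out_cat) < 2L) stop("< 2 out-of-category samples")
  use <- in_t | out_cat
  y <- atlas$expr[gene, use]
  x <- ifelse(in_t[use], 1, -1)
  df_ <- data.frame(y = y, x = x)
  for (cv in covariates) {
    v <- sm[[cv]][use]
    if (length(unique(v)) < 2L) next
    df_[[cv]] <- v
  }
  fit <- stats::lm(y ~ ., data = df_)
  if (anyNA(stats::coef(fit))) {
    # map aliased columns back to their covariate and drop it whole
    asgn <- attr(stats::model.matrix(fit), "assign")
    vars <- c("(Intercept)", attr(stats::terms(fit), "term.labels"))
    bad <- unique(vars[asgn[is.na(stats::coef(fit))] + 1L])
    bad <- setdiff(bad, "x")
    if (length(bad)) {
      warning("dropping collinear covariate(s): ",
              paste(bad, collapse = ", "))
      fit <- stats::lm(y ~ ., data = df_[setdiff(names(df_), bad)])
    }
  }
  s <- summary(fit)$coefficients
  data.frame(gene = gene, tissue = tissue,
             b = s["x", 1L], t = s["x", 3L], pt = s["x", 4L],
             df = fit$df.residual, stringsAsFactors = FALSE)
}

#' Score all genes in all tissues
#'
#' @param atlas an `expression_atlas`.
#' @param genes gene ids (default all).
#' @param tissues tissue names (default all).
#' @param ... passed to [tissue_t()].
#' @return data.frame of class `tissue_scores` (one row per gene x
#'   tissue) with `overexpressed` = (t > 0 and Pt < 1e-4).
#' @export
tissue_scores <- function(atlas, genes = rownames(atlas$expr),
                          tissues = unique(atlas$samples$tissue), ...) {
  rows <- list()
  for (tt in tissues) for (g in genes)
    rows[[length(rows) + 1L]] <- tissue_t(atlas, g, tt, ...)
  res <- do.call(rbind, rows)
  res$overexpressed <- res$t > 0 & res$pt < 1e-4
  class(res) <- c("tissue_scores", "data.frame")
  res
}

#' Per-tissue overexpressed and tissue-specific gene sets
#'
#' Overexpressed: Pt < `pt_cut` (with positive tissue effect).
#' Tissue-specific: the top `top_fraction` of genes by t-statistic in that
#' tissue; set size is `floor(top_fraction * n_genes)` by default
#' (`rounding = "ceiling"` switches the convention).
#'
#' @param scores a `tissue_scores` data.frame.
#' @param top_fraction fraction of genes called tissue-specific (0.10).
#' @param pt_cut overexpression P threshold (1e-4).
#' @param rounding "floor" (default) or "ceiling" for the specific-set
#'   size.
#' @return list of class `specificity_sets`: per tissue, `overexpressed`
#'   and `specific` gene-id vectors, plus `counts` (data.frame per
#'   tissue).
#' @export
specificity_sets <- function(scores, top_fraction = 0.10, pt_cut = 1e-4,
                             rounding = c("floor", "ceiling")) {
  rounding <- match.arg(rounding)
  tissues <- unique(scores$tissue)
  oe <- list(); sp <- list()
  for (tt in tissues) {
    s <- scores[scores$tissue == tt, , drop = FALSE]
    n <- nrow(s)
    k <- if (rounding == "floor") floor(top_fraction * n)
         else ceiling(top_fraction * n)
    oe[[tt]] <- s$gene[s$t > 0 & s$pt < pt_cut]
    sp[[tt]] <- s$gene[order(-s$t)][seq_len(k)]
  }
  counts <- data.frame(tissue = tissues,
                       n_overexpressed = vapply(oe, length, 1L),
                       n_specific = vapply(sp, length, 1L),
                       stringsAsFactors = FALSE)
  structure(list(overexpressed = oe, specific = sp, counts = counts),
            class = "specificity_sets")
}

#' rSNPs whose TF and target gene are both tissue-specific
#'
#' @param calls an `rsnp_calls` table (gain/loss verdicts are kept).
#' @param sets a [specificity_sets()] result.
#' @param tf_target data.frame mapping `tf` to `target_gene` (e.g. the
#'   nearest gene with an upstream call at the variant).
#' @param tissue focal tissue.
#' @param tf_gene_map named character vector translating TF names to
#'   atlas gene ids; TFs without a mapping are excluded and counted in
#'   `attr(x, "n_unmapped")`.
#' @return the subset of `calls` (with `target_gene` merged in) where
#'   both the TF's gene and the target gene are in the focal tissue's
#'   specific set.
#' @export
rsnp_specific_pairs <- function(calls, sets, tf_target, tissue,
                                tf_gene_map = NULL) {
  sp <- sets$specific[[tissue]]
  x <- calls[calls$verdict %in% c("gain", "loss"), , drop = FALSE]
  x <- merge(x, tf_target, by = "tf")
  tf_gene <- if (is.null(tf_gene_map)) x$tf else unname(tf_gene_map[x$tf])
  unmapped <- sum(is.na(tf_gene))
  keep <- !is.na(tf_gene) & tf_gene %in% sp & x$target_gene %in% sp
  res <- x[keep, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "n_unmapped") <- unmapped
  res
}
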