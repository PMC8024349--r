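#' Filter variants on imputation quality and minor allele frequency
#'
#' Retains exactly the variants with imputation R2 >= `r2_min` AND
#' MAF >= `maf_min` (both bounds inclusive), preserving order. The default
#' thresholds are the sequence-GWAS retention rule R2 >= 0.20 and
#' MAF >= 0.005.
#'
#' @param dosages a `dosage_matrix`.
#' @param r2_min minimum imputation R2 (inclusive).
#' @param maf_min minimum MAF (inclusive).
#' @return the filtered `dosage_matrix`; `attr(x, "retention_log")` records
#'   counts in, retained, and removed per rule.
#' @export
filter_variants <- function(dosages, r2_min = 0.20, maf_min = 0.005) {
  map <- dosages$map
  if (any(!is.finite(map$maf)) || any(!is.finite(map$r2))) {
    bad <- map$id[!is.finite(map$maf) | !is.finite(map$r2)]
    stop("missing MAF/R2 for variant(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  keep <- map$r2 >= r2_min & map$maf >= maf_min
  out <- dosages
  out$dosage <- dosages$dosage[, keep, drop = FALSE]
  out$map <- map[keep, , drop = FALSE]
  rownames(out$map) <- NULL
  attr(out, "retention_log") <- data.frame(
    n_in = nrow(map), n_retained = sum(keep),
    n_fail_r2 = sum(map$r2 < r2_min),
    n_fail_maf = sum(map$maf < maf_min))
  class(out) <- "dosage_matrix"
  out
}

#' Genomic relationship matrix (VanRaden method 1)
#'
#' G = M M' / (2 sum p(1-p)) with M the dosage matrix centred by twice the
#' ALT allele frequency. By default the GRM is built from the designated
#' chip ("HD") subset of variants, mirroring the practice of computing the
#' polygenic covariance from high-density array genotypes while sequence
#' variants are tested.
#'
#' @param dosages a `dosage_matrix`.
#' @param subset `"chip"` (default), `"all"`, or a character vector of
#'   variant ids.
#' @return symmetric n x n matrix with cow-id dimnames.
#' @export
compute_grm <- function(dosages, subset = "chip") {
  D <- dosages$dosage
  if (nrow(D) < 2L) stop("GRM needs at least 2 individuals")
  keep <- if (identical(subset, "all")) rep(TRUE, ncol(D))
          else if (identical(subset, "chip")) dosages$map$source == "chip"
          else colnames(D) %in% subset
  D <- D[, keep, drop = FALSE]
  p <- colMeans(D) / 2
  poly <- p > 0 & p < 1
  if (!any(poly)) stop("all selected variants are monomorphic")
  D <- D[, poly, drop = FALSE]; p <- p[poly]
  M <- sweep(D, 2, 2 * p)
  G <- tcrossprod(M) / (2 * sum(p * (1 - p)))
  (G + t(G)) / 2
}

#' Estimate null-model variance components on yield deviations
#'
#' Fits yd = 1 m + u + e with u ~ N(0, G sigma_u^2) by REML, using a single
#' eigendecomposition of the GRM and a 1-D profile-likelihood search in the
#' variance ratio delta = sigma_u^2 / sigma_e^2. The components are then
#' held fixed while each variant is tested.
#'
#' @param yd a `yield_deviation_table` (or data.frame with a `cow` column).
#' @param grm GRM over (at least) the yd cows.
#' @param trait trait column name in `yd`.
#' @return object of class `null_varcomps`: `sigma_u2`, `sigma_e2`,
#'   `h2_genomic`, `loglik`, plus the eigen-rotation (`U`, `d`, `ids`,
#'   rotated phenotype/intercept) reused by [mlma_scan()].
#' @export
fit_null <- function(yd, grm, trait) {
  ids <- intersect(yd$cow, rownames(grm))
  if (length(ids) < 10L) stop("too few cows shared between yd and GRM")
  y <- yd[[trait]][match(ids, yd$cow)]
  G <- grm[ids, ids]
  eg <- eigen(G, symmetric = TRUE)
  d <- pmax(eg$values, 0)
  if (min(eg$values) < -0.05 * max(d))
    stop("GRM strongly non-PSD even after truncation")
  U <- eg$vectors
  ys <- drop(crossprod(U, y))
  xs <- drop(crossprod(U, rep(1, length(y))))
  n <- length(y)
  prof <- function(ldelta) {
    delta <- exp(ldelta)
    v <- d * delta + 1
    w <- 1 / v
    xwx <- sum(xs^2 * w); xwy <- sum(xs * ys * w)
    beta <- xwy / xwx
    rss <- sum(w * (ys - xs * beta)^2)
    s2 <- rss / (n - 1)
    -0.5 * (sum(log(v)) + log(xwx) + (n - 1) * log(s2) + (n - 1))
  }
  opt <- stats::optimize(prof, c(-12, 12), maximum = TRUE, tol = 1e-8)
  delta <- exp(opt$maximum)
  v <- d * delta + 1; w <- 1 / v
  xwx <- sum(xs^2 * w); beta <- sum(xs * ys * w) / xwx
  s2e <- sum(w * (ys - xs * beta)^2) / (n - 1)
  out <- list(sigma_u2 = delta * s2e, sigma_e2 = s2e,
              loglik = opt$objective, U = U, d = d, ids = ids,
              ys = ys, xs = xs, trait = trait)
  # genomic heritability on the observed scale (mean(d) = mean diag of G)
  out$h2_genomic <- out$sigma_u2 * mean(d) /
    (out$sigma_u2 * mean(d) + out$sigma_e2)
  class(out) <- "null_varcomps"
  out
}

#' Mixed-linear-model association scan
#'
#' Tests each variant's additive dosage effect on yield deviations under
#' yd = 1 m + x_v b_v + u + eps with the null-model variance components
#' held fixed: a generalized-least-squares estimate of b_v and its SE are
#' computed in the GRM eigenbasis (O(n) per variant after one rotation of
#' the dosage matrix), the t-statistic is b/SE and the two-sided P-value
#' uses the standard-normal reference by default (`df` switches to an
#' exact t reference for small samples). Zero-variance dosage columns give
#' NA results with a reason code rather than an error.
#'
#' @param yd `yield_deviation_table`.
#' @param dosages `dosage_matrix` of test variants.
#' @param null a [fit_null()] result (defines trait and rotation).
#' @param covariates optional numeric matrix of extra fixed covariates
#'   (rows = cows in `null$ids` order), e.g. a lead-variant dosage for
#'   conditional analysis.
#' @param df `Inf` (normal reference, default) or a finite df for an exact
#'   t reference.
#' @return data.frame of class `gwas_result`: `id`, `chrom`, `pos`, `ref`,
#'   `alt`, `freq` (ALT), `b`, `se`, `t`, `mlog10p`, `maf`, `r2`, `source`,
#'   `reason` (NA or why untested).
#' @export
mlma_scan <- function(yd, dosages, null, covariates = NULL, df = Inf) {
  ids <- null$ids
  D <- dosages$dosage[ids, , drop = FALSE]
  w <- 1 / (null$d * null$sigma_u2 / null$sigma_e2 + 1)  # scaled weights
  X <- cbind(intercept = null$xs)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    X <- cbind(X, crossprod(null$U, covariates))
  }
  ys <- null$ys
  Ds <- crossprod(null$U, D)                   # n x m rotation
  q <- ncol(X)
  Xw <- X * w
  XtWX <- crossprod(X, Xw)
  XtWXi <- solve(XtWX)
  XtWy <- crossprod(Xw, ys)
  A <- crossprod(Xw, Ds)                       # q x m
  cvec <- colSums(Ds * (w * Ds))
  dvec <- drop(crossprod(Ds, w * ys))
  u <- drop(XtWXi %*% XtWy)
  den <- cvec - colSums(A * (XtWXi %*% A))
  num <- dvec - drop(crossprod(A, u))
  ok <- den > 1e-10 * max(cvec, 1)
  b <- ifelse(ok, num / den, NA_real_)
  # variance of b under known V: sigma_e2 * (x' V^-1_adj x)^-1 in scaled units
  se <- ifelse(ok, sqrt(null$sigma_e2 / den), NA_real_)
  tt <- b / se
  mlog10p <- if (is.finite(df)) -(stats::pt(abs(tt), df = df,
                                            lower.tail = FALSE, log.p = TRUE) +
                                  log(2)) / log(10)
             else -(stats::pnorm(abs(tt), lower.tail = FALSE, log.p = TRUE) +
                    log(2)) / log(10)
  map <- dosages$map
  out <- data.frame(id = map$id, chrom = map$chrom, pos = map$pos,
                    ref = map$ref, alt = map$alt,
                    freq = colMeans(D) / 2,
                    b = b, se = se, t = tt, mlog10p = mlog10p,
                    maf = map$maf, r2 = map$r2, source = map$source,
                    reason = ifelse(ok, NA_character_, "zero_variance"),
                    stringsAsFactors = FALSE)
  attr(out, "trait") <- null$trait
  class(out) <- c("gwas_result", "data.frame")
  out
}
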