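#' Hard genotype calls from allele dosages
#'
#' Rounds dosages to 0/1/2 and drops uncertain calls: dosages in
#' (0.2, 0.8) or (1.2, 1.8) become NA.
#'
#' @param dosage numeric vector in \[0, 2\].
#' @param lo,hi uncertainty band half-bounds (defaults 0.2 / 0.8).
#' @return integer vector of genotype classes with NAs for uncertain.
#' @export
hard_call <- function(dosage, lo = 0.2, hi = 0.8) {
  g <- as.integer(round(dosage))
  frac <- dosage - floor(dosage)
  uncertain <- (frac > lo & frac < hi)
  g[uncertain] <- NA_integer_
  g
}

#' Two-locus genotype-interaction test on yield deviations
#'
#' Fits the mixed linear model
#'   yd = m + g1 + g2 + g1 x g2 + sire + e
#' with fixed genotype-class factors for the two loci and their
#' interaction, and a random sire intercept (REML via lme4; when `sire`
#' is NULL or has a single level the model reduces to fixed effects only
#' and matches the two-way ANOVA fit). Main effects and the interaction
#' are tested with Wald chi-square statistics on the corresponding
#' coefficient blocks (each coefficient also carries its own
#' t-statistic); empty genotype cells simply drop their contrasts. The
#' 3 x 3 grid of model-based cell means with SEs and per-cell counts is
#' returned for plotting.
#'
#' @param yd numeric response (one trait's yield deviations).
#' @param geno1,geno2 genotype vectors (hard calls 0/1/2; NAs dropped).
#' @param sire factor of sire identities (or NULL).
#' @return object of class `interaction_result`: `tests` (data.frame for
#'   locus1, locus2, interaction: `wald`, `df`, `p`), `coefficients`
#'   (estimate, SE, t per fixed coefficient), `cell_means` (g1, g2, mean,
#'   se, n), `sigma_sire2`, `sigma_e2`, `n_used`.
#' @export
interaction_test <- function(yd, geno1, geno2, sire = NULL) {
  ok <- is.finite(yd) & !is.na(geno1) & !is.na(geno2)
  if (!is.null(sire)) ok <- ok & !is.na(sire)
  y <- yd[ok]
  g1 <- factor(geno1[ok]); g2 <- factor(geno2[ok])
  if (nlevels(g1) < 2L || nlevels(g2) < 2L)
    stop("both loci must have >= 2 populated genotype classes")
  s <- if (!is.null(sire)) factor(sire[ok]) else NULL
  use_sire <- !is.null(s) && nlevels(s) >= 2L
  dat <- data.frame(y = y, g1 = g1, g2 = g2)
  if (use_sire) dat$s <- s
  if (use_sire) {
    fit <- lme4::lmer(y ~ g1 * g2 + (1 | s), data = dat, REML = TRUE,
                      control = lme4::lmerControl(calc.derivs = FALSE,
                                                  check.conv.singular = "ignore"))
    b <- lme4::fixef(fit)
    V <- as.matrix(stats::vcov(fit))
    asgn <- attr(lme4::getME(fit, "X"), "assign")
    vc <- lme4::VarCorr(fit)
    sigma_s2 <- as.numeric(vc$s)
    sigma_e2 <- stats::sigma(fit)^2
  } else {
    fit <- stats::lm(y ~ g1 * g2, data = dat)
    keep <- !is.na(stats::coef(fit))
    b <- stats::coef(fit)[keep]
    V <- stats::vcov(fit, complete = FALSE)
    asgn <- attr(stats::model.matrix(fit), "assign")[keep]
    sigma_s2 <- 0
    sigma_e2 <- stats::sigma(fit)^2
  }
  terms_ <- c("(Intercept)", "g1", "g2", "g1:g2")
  wald_block <- function(term_i) {
    j <- which(asgn == term_i)
    if (!length(j)) return(c(NA_real_, 0, NA_real_))
    W <- drop(t(b[j]) %*% solve(V[j, j, drop = FALSE]) %*% b[j])
    c(W, length(j), stats::pchisq(W, length(j), lower.tail = FALSE))
  }
  tw <- t(vapply(1:3, wald_block, numeric(3)))
  tests <- data.frame(effect = c("locus1", "locus2", "interaction"),
                      wald = tw[, 1], df = as.integer(tw[, 2]), p = tw[, 3],
                      stringsAsFactors = FALSE)
  coefs <- data.frame(term = names(b), estimate = unname(b),
                      se = sqrt(diag(V)),
                      stringsAsFactors = FALSE)
  coefs$t <- coefs$estimate / coefs$se
  # model-based cell means over observed genotype combinations
  grid <- unique(dat[, c("g1", "g2")])
  grid <- grid[order(grid$g1, grid$g2), , drop = FALSE]
  Xg <- stats::model.matrix(~ g1 * g2, grid)
  Xg <- Xg[, names(b), drop = FALSE]
  mu <- drop(Xg %*% b)
  se_mu <- sqrt(rowSums((Xg %*% V) * Xg))
  ncell <- mapply(function(a, b2) sum(dat$g1 == a & dat$g2 == b2),
                  grid$g1, grid$g2)
  cells <- data.frame(g1 = as.character(grid$g1), g2 = as.character(grid$g2),
                      mean = mu, se = se_mu, n = as.integer(ncell),
                      stringsAsFactors = FALSE)
  structure(list(tests = tests, coefficients = coefs, cell_means = cells,
                 sigma_sire2 = sigma_s2, sigma_e2 = sigma_e2,
                 n_used = length(y)),
            class = "interaction_result")
}
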