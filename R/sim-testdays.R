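#' Simulate repeated test-day phenotype records
#'
#' Each phenotyped cow receives between `records_per_cow[1]` and
#' `records_per_cow[2]` test-day records. A record for trait t is
#'
#'   y = mu_t + htd + stage + season + g + pe + e
#'
#' with a herd x test-day fixed effect (cows are nested in herds; herds
#' share monthly test days), a lactation-stage effect (5 stages along the
#' record sequence), a season-of-calving effect (4 seasons per cow), the
#' additive genetic value g (pedigree polygenic value from N(0, A x G0)
#' drawn by recursive Mendelian sampling, plus centred planted-QTL
#' contributions), a permanent-environment effect pe ~ N(0, P0) per cow and
#' a residual e ~ N(0, R0) per record. Multi-trait draws use the Cholesky
#' factors of the configured (co)variance matrices, so phenotypic variance
#' is ~1 per trait and heritability matches `h2_targets` up to the planted
#' QTL, which sit on top of the polygenic variance.
#'
#' @param config a [sim_config()].
#' @param pedigree from [simulate_pedigree()].
#' @param dosages from [simulate_dosages()].
#' @param truth from [plant_qtl()]; its `tbv` slot is filled on return via
#'   the attribute `truth` of the result.
#' @return a `data.frame` of class `test_day_table` with columns `cow`,
#'   `herd`, `test_day`, `htd`, `stage`, `season` and one column per trait
#'   (named `Ca`, `P`, `Mg`, `K`, `Na`, `Citrate` for six traits, `T1`...
#'   otherwise). The completed [plant_qtl()] ground truth (with
#'   `tbv` = true breeding values, cows x traits) is attached as
#'   `attr(x, "truth")`.
#' @export
simulate_test_days <- function(config, pedigree, dosages, truth) {
  config <- validate_sim_config(config)
  set.seed(sim_subseed(config$seed, 4L))
  vc <- truth$varcomps
  nt <- config$n_traits
  LG <- t(chol(vc$G0 + diag(1e-10, nt)))
  LP <- t(chol(vc$P0 + diag(1e-10, nt)))
  LR <- t(chol(vc$R0 + diag(1e-10, nt)))

  sp <- pedigree_sort(pedigree)
  n_anim <- nrow(sp)
  idx <- seq_len(n_anim); names(idx) <- sp$id
  si <- idx[sp$sire]; di <- idx[sp$dam]
  f <- inbreeding_coefs(sp)

  # polygenic values by recursive Mendelian sampling, multi-trait
  a <- matrix(0, n_anim, nt)
  z <- matrix(stats::rnorm(n_anim * nt), n_anim, nt) %*% t(LG)
  for (i in seq_len(n_anim)) {
    s <- si[i]; d <- di[i]
    if (is.na(s) && is.na(d)) { a[i, ] <- z[i, ]; next }
    pa <- 0; w <- 1
    fs <- if (!is.na(s)) f[s] else -1
    fd <- if (!is.na(d)) f[d] else -1
    if (!is.na(s)) pa <- pa + 0.5 * a[s, ]
    if (!is.na(d)) pa <- pa + 0.5 * a[d, ]
    w <- sqrt(0.5 - 0.25 * (fs + fd))
    a[i, ] <- pa + w * z[i, ]
  }
  rownames(a) <- sp$id

  cows <- rownames(dosages$dosage)
  nc <- length(cows)
  # centred planted-QTL contributions
  qg <- matrix(0, nc, nt)
  if (nrow(truth$qtl)) {
    for (k in seq_len(nrow(truth$qtl))) {
      q <- truth$qtl[k, ]
      x <- dosages$dosage[, q$id]
      qg[, q$trait] <- qg[, q$trait] + (x - 2 * q$alt_freq) * q$b
    }
  }
  tbv <- a[cows, , drop = FALSE] + qg
  truth$tbv <- tbv

  pe <- matrix(stats::rnorm(nc * nt), nc, nt) %*% t(LP)

  rr <- config$records_per_cow
  nrec <- if (rr[1] == rr[2]) rep(rr[1], nc)
          else sample(seq(rr[1], rr[2]), nc, replace = TRUE)
  herd <- sample(seq_len(config$n_herds), nc, replace = TRUE)
  season <- sample(1:4, nc, replace = TRUE)
  season_eff <- stats::rnorm(4, 0, 0.15)
  stage_eff <- stats::rnorm(5, 0, 0.2)
  mu <- if (nt == 6) c(Ca = 1.20, P = 0.95, Mg = 0.11, K = 1.55,
                       Na = 0.42, Citrate = 1.60)
        else stats::setNames(rep(10, nt), paste0("T", seq_len(nt)))
  tn <- names(mu)

  cow_i <- rep(seq_len(nc), nrec)
  rec_j <- sequence(nrec)
  n_rec <- length(cow_i)
  # monthly test days per herd; start month varies by cow within 1..3
  month <- sample(1:3, nc, replace = TRUE)[cow_i] + rec_j - 1L
  htd <- paste0("h", herd[cow_i], "m", month)
  htd_lv <- unique(htd)
  htd_eff <- stats::setNames(stats::rnorm(length(htd_lv), 0, sqrt(config$var_htd)), htd_lv)
  stage <- pmin(5L, 1L + (rec_j - 1L) %/% 2L)

  e <- matrix(stats::rnorm(n_rec * nt), n_rec, nt) %*% t(LR)
  y <- matrix(rep(mu, each = n_rec), n_rec, nt) +
    htd_eff[htd] + stage_eff[stage] + season_eff[season[cow_i]] +
    tbv[cow_i, , drop = FALSE] + pe[cow_i, , drop = FALSE] + e
  colnames(y) <- tn

  out <- data.frame(cow = cows[cow_i], herd = herd[cow_i],
                    test_day = month, htd = htd, stage = stage,
                    season = season[cow_i], stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(y))
  class(out) <- c("test_day_table", "data.frame")
  attr(out, "truth") <- truth
  attr(out, "trait_names") <- tn
  out
}
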