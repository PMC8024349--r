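#' Simulate LD-structured allele dosages through a pedigree
#'
#' Variants are laid out on `n_chromosomes` chromosomes and grouped into LD
#' blocks of `ld_block_len` bp. Each block carries one founder "core"
#' biallelic locus; every variant in the block is a copy of the core
#' haplotype signal with independent per-haplotype flip noise (probability
#' `flip_rate`), so adjacent variants within a block are in strong LD while
#' blocks are independent. With `gene_drop = TRUE` (default) core alleles
#' are transmitted through the pedigree by Mendelian sampling; otherwise
#' every animal draws independent Hardy-Weinberg genotypes.
#'
#' Each variant carries an empirical MAF and an assigned imputation R2:
#' a designated `chip_frac` subset is flagged `"chip"` with R2 = 1, the
#' rest are `"imputed"` with Beta(2,1)-distributed R2 (mean 2/3). Variants
#' that come out monomorphic are dropped (counted in `attr(.,"n_dropped")`).
#'
#' @param config a [sim_config()].
#' @param pedigree output of [simulate_pedigree()].
#' @return object of class `dosage_matrix`: list with `dosage` (phenotyped
#'   cows x variants, values in \[0,2\]), `map` (data.frame: `id`, `chrom`,
#'   `pos`, `ref`, `alt`, `maf`, `r2`, `source`, `block`), `core_dosage`
#'   (all animals x blocks core-locus dosages, for pedigree-transmission
#'   checks) and `block_freq` (founder allele frequency per block).
#' @export
simulate_dosages <- function(config, pedigree) {
  config <- validate_sim_config(config)
  set.seed(sim_subseed(config$seed, 2L))
  sp <- pedigree_sort(pedigree)
  n_anim <- nrow(sp)
  idx <- seq_len(n_anim); names(idx) <- sp$id
  si <- idx[sp$sire]; di <- idx[sp$dam]

  m <- config$n_variants
  chrom <- sort(rep_len(seq_len(config$n_chromosomes), m))
  pos <- unlist(lapply(split(seq_len(m), chrom), function(ix)
    sort(sample.int(config$chrom_len, length(ix)))), use.names = FALSE)
  block_of <- paste0(chrom, "_", (pos - 1) %/% config$ld_block_len)
  blocks <- unique(block_of)
  b_idx <- match(block_of, blocks)
  nb <- length(blocks)

  p0 <- stats::runif(nb, 0.05, 0.5)
  if (any(p0 <= 0)) stop("block founder frequency of 0 requested: monomorphic")

  # core haplotypes per block for every animal
  H1 <- matrix(0L, n_anim, nb)
  H2 <- matrix(0L, n_anim, nb)
  founder <- is.na(si) & is.na(di)
  H1[founder, ] <- matrix(stats::rbinom(sum(founder) * nb, 1L, rep(p0, each = sum(founder))), ncol = nb)
  H2[founder, ] <- matrix(stats::rbinom(sum(founder) * nb, 1L, rep(p0, each = sum(founder))), ncol = nb)
  if (config$gene_drop) {
    for (i in which(!founder)) {
      s <- si[i]; d <- di[i]
      pick_s <- stats::runif(nb) < 0.5
      pick_d <- stats::runif(nb) < 0.5
      hs <- if (!is.na(s)) ifelse(pick_s, H1[s, ], H2[s, ])
            else stats::rbinom(nb, 1L, p0)
      hd <- if (!is.na(d)) ifelse(pick_d, H1[d, ], H2[d, ])
            else stats::rbinom(nb, 1L, p0)
      H1[i, ] <- hs; H2[i, ] <- hd
    }
  } else {
    nf <- which(!founder)
    H1[nf, ] <- matrix(stats::rbinom(length(nf) * nb, 1L, rep(p0, each = length(nf))), ncol = nb)
    H2[nf, ] <- matrix(stats::rbinom(length(nf) * nb, 1L, rep(p0, each = length(nf))), ncol = nb)
  }

  cows <- sp$id[sp$phenotyped]
  ci <- idx[cows]
  nc <- length(ci)
  # expand blocks to variants with flip noise on each haplotype copy
  D <- matrix(0, nc, m)
  fr <- config$flip_rate
  for (v in seq_len(m)) {
    b <- b_idx[v]
    f1 <- stats::rbinom(nc, 1L, fr)
    f2 <- stats::rbinom(nc, 1L, fr)
    D[, v] <- xor(H1[ci, b], f1) + xor(H2[ci, b], f2)
  }
  af <- colMeans(D) / 2
  keep <- af > 0 & af < 1
  n_dropped <- sum(!keep)
  D <- D[, keep, drop = FALSE]
  chrom <- chrom[keep]; pos <- pos[keep]; b_idx <- b_idx[keep]
  af <- af[keep]
  m <- ncol(D)

  acgt <- c("A", "C", "G", "T")
  ref <- sample(acgt, m, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(acgt, r), 1L), "")
  ids <- sprintf("%d:%d", chrom, pos)
  n_chip <- max(1L, round(config$chip_frac * m))
  chip <- seq_len(m) %in% round(seq(1L, m, length.out = n_chip))
  r2 <- ifelse(chip, 1, stats::rbeta(m, 2, 1))
  r2 <- pmax(r2, 1e-3)
  map <- data.frame(id = ids, chrom = chrom, pos = pos, ref = ref, alt = alt,
                    maf = pmin(af, 1 - af), alt_freq = af, r2 = r2,
                    source = ifelse(chip, "chip", "imputed"),
                    block = b_idx, stringsAsFactors = FALSE)
  dimnames(D) <- list(cows, ids)
  core <- H1 + H2
  dimnames(core) <- list(sp$id, blocks)
  out <- list(dosage = D, map = map, core_dosage = core, block_freq = p0)
  attr(out, "n_dropped") <- n_dropped
  class(out) <- "dosage_matrix"
  out
}

#' Plant causal QTL into simulated dosages
#'
#' Picks `n_qtl` causal variants, maximally spread across the genome (one
#' per distant block, preferring common, well-imputed variants so planted
#' signals are detectable), assigns them to traits round-robin, and draws
#' allele-substitution effects. When `qtl_var_frac` is set, each effect is
#' sized so the QTL explains that fraction of the trait's additive variance
#' (|b| = sqrt(frac * h2 / (2p(1-p))), phenotypic variance 1); otherwise
#' effects are N(0, qtl_effect_sd^2).
#'
#' @param config a [sim_config()].
#' @param dosages a [simulate_dosages()] result.
#' @return object of class `ground_truth` with `qtl` (data.frame: `id`,
#'   `chrom`, `pos`, `trait`, `b`, `alt_freq`), `varcomps`
#'   (from [true_varcomps()]), and empty slots `tbv` and
#'   `overexpressed_gene_map` filled by later generators.
#' @export
plant_qtl <- function(config, dosages) {
  config <- validate_sim_config(config)
  set.seed(sim_subseed(config$seed, 3L))
  map <- dosages$map
  if (config$n_qtl > nrow(map)) stop("fewer variants than requested QTL")
  cand <- which(map$maf >= 0.15 & map$r2 >= 0.8)
  if (length(cand) < config$n_qtl) cand <- order(-map$maf)[seq_len(max(config$n_qtl, 50L))]
  # spread: rank candidates on a genome-wide coordinate, take evenly spaced
  gpos <- map$chrom[cand] * (config$chrom_len * 1.1) + map$pos[cand]
  o <- cand[order(gpos)]
  pick <- o[unique(round(seq(1, length(o), length.out = config$n_qtl)))]
  while (length(pick) < config$n_qtl)
    pick <- unique(c(pick, sample(cand, 1L)))
  trait <- rep_len(seq_len(config$n_traits), config$n_qtl)
  p <- map$alt_freq[pick]
  if (!is.null(config$qtl_var_frac)) {
    b <- sqrt(config$qtl_var_frac * config$h2_targets[trait] / (2 * p * (1 - p)))
    b <- b * sample(c(-1, 1), config$n_qtl, replace = TRUE)
  } else {
    b <- stats::rnorm(config$n_qtl, 0, config$qtl_effect_sd)
  }
  truth <- list(
    qtl = data.frame(id = map$id[pick], chrom = map$chrom[pick],
                     pos = map$pos[pick], trait = trait, b = b,
                     alt_freq = p, stringsAsFactors = FALSE),
    varcomps = true_varcomps(config),
    tbv = NULL, overexpressed_gene_map = NULL)
  class(truth) <- "ground_truth"
  truth
}
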