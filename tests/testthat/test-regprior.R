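test_that("uniform PWM scores zero everywhere; consensus score is the log-odds sum", {
  u <- pwm("U", matrix(25, 4, 8))
  set.seed(2)
  sq <- paste(sample(c("A", "C", "G", "T"), 40, TRUE), collapse = "")
  expect_equal(scan_pwm(sq, u)$score, 0, tolerance = 1e-12)
  # consensus planted at offset 7 is found with the hand-computed score
  cm <- matrix(2, 4, 8, dimnames = list(c("A", "C", "G", "T"), NULL))
  cons <- c("A", "C", "G", "T", "A", "C", "G", "T")
  for (j in 1:8) cm[cons[j], j] <- 94
  p <- pwm("P", cm)
  hand <- 8 * log2(((94 + 0.8 * 0.25) / (100 + 0.8)) / 0.25)
  left <- "TTTTTTT"   # consensus-free flank
  emb <- paste0(left, paste(cons, collapse = ""), "TTTTT")
  sc <- scan_pwm(emb, p)
  expect_equal(sc$score, hand, tolerance = 1e-10)
  expect_equal(sc$offset, 7)
  expect_equal(sc$strand, "+")
})

test_that("scan_pwm equals the brute-force enumeration oracle", {
  st <- get_small_study()
  set.seed(17)
  for (p in st$pwms[1:4]) {
    for (rep in 1:3) {
      sq <- paste(sample(c("A", "C", "G", "T"), p$length + 15, TRUE),
                  collapse = "")
      expect_equal(scan_pwm(sq, p)$score, scan_oracle(sq, p),
                   tolerance = 1e-10)
    }
  }
})

test_that("reverse-complementing the input preserves score and flips strand", {
  st <- get_small_study()
  p <- st$pwms[[1]]
  set.seed(21)
  sq <- paste(sample(c("A", "C", "G", "T"), 30, TRUE), collapse = "")
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(sq)))
  s1 <- scan_pwm(sq, p); s2 <- scan_pwm(rc, p)
  expect_equal(s1$score, s2$score, tolerance = 1e-10)
  # ambiguous bases are tolerated and counted
  s3 <- scan_pwm(sub("^.", "N", sq), p)
  expect_equal(s3$n_ambiguous, 1)
})

test_that("exact 8-mer null matches Monte Carlo within 1e-3", {
  cm <- matrix(sample(1:40, 32, replace = TRUE), 4, 8,
               dimnames = list(c("A", "C", "G", "T"), NULL))
  set.seed(77)
  p <- pwm("X", cm)
  exact <- pwm_null(p, exact_max = 12)
  expect_equal(attr(exact, "method"), "exact")
  sampled <- pwm_null(p, exact_max = 0, n_sample = 2e5)
  expect_equal(attr(sampled, "method"), "sample")
  qs <- quantile(replicate(50, scan_oracle(
    paste(sample(c("A", "C", "G", "T"), 8, TRUE), collapse = ""), p)),
    c(0.25, 0.5, 0.75))
  for (s in c(qs, 0)) {
    expect_lt(abs(exact(s) - sampled(s)), 1e-3 + 3 * sqrt(0.25 / 2e5) + 2e-3)
  }
  # the exact tail probabilities behave like probabilities
  expect_equal(exact(-1e6), 1)
  expect_equal(exact(1e6), 0)
})

test_that("consensus-destroying substitutions are called as losses", {
  # sharp 8-mer so one substitution moves the site across the significance
  # line: a perfect match is rarer than p_site, a 7/8 match is not
  cm <- matrix(1, 4, 8, dimnames = list(c("A", "C", "G", "T"), NULL))
  cons <- c("A", "C", "G", "T", "T", "G", "C", "A")
  for (j in 1:8) cm[cons[j], j] <- 97
  lib <- structure(list(TFX = pwm("TFX", cm)), class = "pwm_library")
  p_site <- 1e-4   # between P(perfect ~ 1.5e-5) and P(7/8 match ~ 4e-4)
  set.seed(31)
  flank <- paste(sample(c("T", "T", "G", "A"), 30, TRUE), collapse = "")
  seqstr <- paste0(flank, paste(cons, collapse = ""), flank)
  genome <- Biostrings::DNAStringSet(seqstr); names(genome) <- "1"
  vpos <- nchar(flank) + 2L   # motif position 2 (consensus C)
  v <- data.frame(chrom = "1", pos = vpos, ref = "C", alt = "G")
  calls <- tfbs_alteration(v, genome, lib, p_site = p_site)
  expect_equal(calls$verdict, "loss")
  expect_lt(calls$p_ref, p_site)
  expect_gte(calls$p_alt, p_site)
  # swapping ref/alt (with the alt allele written into the genome) turns
  # the loss into a gain
  v2 <- data.frame(chrom = "1", pos = vpos, ref = "G", alt = "C")
  g2 <- Biostrings::DNAStringSet(`substr<-`(seqstr, vpos, vpos, "G"))
  names(g2) <- "1"
  calls2 <- tfbs_alteration(v2, g2, lib, p_site = p_site)
  expect_equal(calls2$verdict, "gain")
})

test_that("edge variants are skipped with a log entry", {
  st <- get_small_study()
  genome <- Biostrings::DNAStringSet("ACGTACGTAC"); names(genome) <- "1"
  v <- data.frame(chrom = "1", pos = 2, ref = "C", alt = "T")
  calls <- tfbs_alteration(v, genome, st$pwms[1])
  expect_equal(nrow(calls), 0)
  expect_gt(length(attr(calls, "skipped")), 0)
})

test_that("tissue_t equals the classical two-sample t without covariates", {
  st <- get_small_study()
  atlas <- st$atlas
  g <- rownames(atlas$expr)[5]
  tt <- tissue_t(atlas, g, "liver", covariates = NULL)
  sm <- atlas$samples
  cat_l <- sm$category[match("liver", sm$tissue)]
  x1 <- atlas$expr[g, sm$tissue == "liver"]
  x0 <- atlas$expr[g, sm$category != cat_l]
  tcl <- t.test(x1, x0, var.equal = TRUE)
  expect_equal(abs(tt$t), abs(unname(tcl$statistic)), tolerance = 1e-10)
  expect_equal(tt$pt, tcl$p.value, tolerance = 1e-10)
})

test_that("planted overexpression is detected; flat genes are not", {
  st <- get_small_study()
  atlas <- st$atlas
  oe <- atlas$overexpressed_gene_map[["mammary gland"]]
  tt <- tissue_t(atlas, oe[1], "mammary gland")
  expect_lt(tt$pt, 1e-4)
  expect_gt(tt$t, 0)
  # a gene planted nowhere near mammary gland
  flat <- setdiff(rownames(atlas$expr),
                  unlist(atlas$overexpressed_gene_map))[1]
  t0 <- tissue_t(atlas, flat, "mammary gland")
  expect_gt(t0$pt, 1e-4)
})

test_that("collinear covariates are dropped with a warning", {
  st <- get_small_study()
  atlas <- st$atlas
  atlas$samples$age <- 1  # constant: silently skipped (no variance)
  expect_silent(tissue_t(atlas, rownames(atlas$expr)[1], "liver"))
  # a covariate perfectly collinear with the tissue indicator
  cat_l <- atlas$samples$category[match("liver", atlas$samples$tissue)]
  use <- atlas$samples$tissue == "liver" | atlas$samples$category != cat_l
  atlas$samples$age <- ifelse(atlas$samples$tissue == "liver", 5, 2)
  expect_warning(tissue_t(atlas, rownames(atlas$expr)[1], "liver"),
                 "collinear")
})

test_that("specific-set sizes follow the floor(10%) rule", {
  mk_scores <- function(n) {
    data.frame(gene = paste0("g", 1:n), tissue = "t1",
               t = rnorm(n), pt = runif(n), stringsAsFactors = FALSE)
  }
  set.seed(12)
  expect_equal(length(specificity_sets(mk_scores(203))$specific$t1), 20)
  expect_equal(length(specificity_sets(mk_scores(160))$specific$t1), 16)
  expect_equal(length(specificity_sets(mk_scores(200))$specific$t1), 20)
  expect_equal(length(specificity_sets(
    mk_scores(203), rounding = "ceiling")$specific$t1), 21)
  # all Pt = 1 gives empty overexpressed sets
  s <- mk_scores(50); s$pt <- 1
  expect_equal(length(specificity_sets(s)$overexpressed$t1), 0)
})

test_that("planted overexpressed genes are recovered per tissue", {
  st <- get_small_study()
  atlas <- st$atlas
  tiss <- c("mammary gland", "liver")
  genes <- unique(c(unlist(atlas$overexpressed_gene_map[tiss]),
                    rownames(atlas$expr)[1:10]))
  sc <- tissue_scores(atlas, genes = genes, tissues = tiss)
  sets <- specificity_sets(sc)
  for (tt in tiss) {
    planted <- atlas$overexpressed_gene_map[[tt]]
    expect_true(all(planted %in% sets$overexpressed[[tt]]))
  }
})

test_that("rsnp/tissue-specific pair filtering applies both conditions", {
  calls <- data.frame(id = c("v1", "v2", "v3"), tf = c("TF1", "TF2", "TF3"),
                      verdict = c("loss", "gain", "none"),
                      stringsAsFactors = FALSE)
  sets <- structure(list(specific = list(mam = c("G1", "G2", "T1"))),
                    class = "specificity_sets")
  tf_target <- data.frame(tf = c("TF1", "TF2", "TF3"),
                          target_gene = c("G1", "G9", "G1"),
                          stringsAsFactors = FALSE)
  map <- c(TF1 = "T1", TF2 = "T1")  # TF3 unmapped
  out <- rsnp_specific_pairs(calls, sets, tf_target, "mam", map)
  expect_equal(out$id, "v1")               # TF2 fails on target gene
  expect_equal(attr(out, "n_unmapped"), 0) # TF3 dropped earlier (verdict none)
  # empty specific sets give empty output
  sets0 <- structure(list(specific = list(mam = character(0))),
                     class = "specificity_sets")
  expect_equal(nrow(rsnp_specific_pairs(calls, sets0, tf_target, "mam", map)), 0)
})
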