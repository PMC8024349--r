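test_that("config validation rejects impossible designs", {
  expect_error(sim_config(n_sires = 0), "n_sires")
  expect_error(sim_config(n_cows = 10, n_sires = 10), "n_sires must be <")
  expect_error(sim_config(h2_targets = c(0, 0.5)), "h2_targets")
  bad_rg <- matrix(c(1, 2, 2, 1), 2)
  expect_error(sim_config(n_traits = 2, h2_targets = c(.4, .4),
                          rg_matrix = bad_rg), "semi-definite")
  expect_error(sim_config(n_variants = 2, n_qtl = 5), "n_variants")
})

test_that("simulated pedigree is deterministic, acyclic, with founder structure", {
  cfg <- small_config()
  p1 <- simulate_pedigree(cfg)
  p2 <- simulate_pedigree(cfg)
  expect_identical(p1, p2)
  expect_true(all(is.na(p1$sire[p1$generation == 0])))
  expect_gte(max(p1$generation), 2)
  expect_silent(pedigree_sort(p1))  # acyclic by construction
  expect_equal(sum(p1$phenotyped), cfg$n_cows)
})

test_that("single shared sire gives half-sib relationship 0.25", {
  ped <- data.frame(id = c("S1", paste0("D", 1:4), paste0("C", 1:4)),
                    sire = c(NA, rep(NA, 4), rep("S1", 4)),
                    dam = c(NA, rep(NA, 4), paste0("D", 1:4)))
  A <- build_A(ped)
  cows <- paste0("C", 1:4)
  off <- A[cows, cows][upper.tri(diag(4))]
  expect_equal(unname(off), rep(0.25, 6))
})

test_that("4-generation pedigree has low inbreeding (mean diagonal in [1, 1.1])", {
  cfg <- sim_config(seed = 2, n_cows = 200, n_sires = 10, n_generations = 4,
                    n_variants = 50)
  ped <- simulate_pedigree(cfg)
  A <- build_A(ped[, c("id", "sire", "dam")])
  expect_gte(mean(diag(A)), 1.0)
  expect_lte(mean(diag(A)), 1.1)
})

test_that("dosages are deterministic, bounded, polymorphic, with chip R2 = 1", {
  cfg <- small_config()
  ped <- simulate_pedigree(cfg)
  d1 <- simulate_dosages(cfg, ped)
  d2 <- simulate_dosages(cfg, ped)
  expect_identical(d1$dosage, d2$dosage)
  expect_true(all(d1$dosage >= 0 & d1$dosage <= 2))
  expect_true(all(d1$map$maf > 0 & d1$map$maf <= 0.5))
  expect_true(all(d1$map$r2 > 0 & d1$map$r2 <= 1))
  expect_true(all(d1$map$r2[d1$map$source == "chip"] == 1))
})

test_that("within-block adjacent variants are in strong LD", {
  cfg <- small_config(seed = 7)
  ped <- simulate_pedigree(cfg)
  dos <- simulate_dosages(cfg, ped)
  m <- dos$map
  r2 <- c()
  for (b in unique(m$block)) {
    ix <- which(m$block == b)
    if (length(ix) < 2) next
    for (k in seq_len(length(ix) - 1))
      r2 <- c(r2, cor(dos$dosage[, ix[k]], dos$dosage[, ix[k + 1]])^2)
  }
  # 1% flip noise per haplotype: adjacent pairs share a block core
  expect_gt(mean(r2), 0.5)
  expect_gt(median(r2), 0.9)
})

test_that("gene-drop transmission: offspring core dosage centres on parent mean", {
  cfg <- small_config(seed = 9)
  ped <- simulate_pedigree(cfg)
  dos <- simulate_dosages(cfg, ped)
  core <- dos$core_dosage
  kids <- ped[!is.na(ped$sire) & !is.na(ped$dam), ]
  kids <- kids[kids$sire %in% rownames(core) & kids$dam %in% rownames(core), ]
  dev <- core[kids$id, ] - (core[kids$sire, ] + core[kids$dam, ]) / 2
  expect_lt(abs(mean(dev)), 0.05)
})

test_that("test-day records have the configured structure and heritable signal", {
  st <- get_small_study()
  td <- st$test_days
  cnt <- table(td$cow)
  expect_true(all(cnt >= st$config$records_per_cow[1] &
                  cnt <= st$config$records_per_cow[2]))
  truth <- st$truth
  # phenotypic cow means correlate with true breeding values
  cm <- tapply(td$T1, td$cow, mean)
  r <- cor(cm[rownames(truth$tbv)], truth$tbv[, 1])
  expect_gt(r, 0.4)
})

test_that("pure-residual simulation carries no genetic signal", {
  cfg <- small_config(seed = 33)
  cfg$h2_targets <- c(1e-3, 1e-3); cfg$pe_frac <- c(1e-3, 1e-3)
  cfg$n_qtl <- 0L
  ped <- simulate_pedigree(cfg)
  dos <- simulate_dosages(cfg, ped)
  td <- simulate_test_days(cfg, ped, dos, plant_qtl(cfg, dos))
  truth <- attr(td, "truth")
  expect_lt(var(truth$tbv[, 1]), 0.01)
})

test_that("planted QTL effects have the requested variance share", {
  cfg <- small_config(seed = 12, qtl_var_frac = 0.10)
  ped <- simulate_pedigree(cfg)
  dos <- simulate_dosages(cfg, ped)
  truth <- plant_qtl(cfg, dos)
  q <- truth$qtl[1, ]
  expect_equal(2 * q$alt_freq * (1 - q$alt_freq) * q$b^2,
               0.10 * cfg$h2_targets[q$trait], tolerance = 1e-10)
})

test_that("simulated CDS translate cleanly on both strands", {
  st <- get_small_study()
  ann <- st$annotation
  g <- ann$genes
  strands_seen <- character(0)
  for (tid in unique(g$transcript_id[g$type == "CDS"])) {
    cds <- g[g$transcript_id == tid & g$type == "CDS", ]
    cds <- cds[order(cds$start), ]
    s <- paste(vapply(seq_len(nrow(cds)), function(i)
      as.character(Biostrings::subseq(ann$genome[[as.character(cds$chrom[i])]],
                                      cds$start[i], cds$end[i])), ""),
      collapse = "")
    if (cds$strand[1] == "-")
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    strands_seen <- union(strands_seen, cds$strand[1])
    expect_equal(nchar(s) %% 3, 0)
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(s)))
    expect_equal(substr(aa, 1, 1), "M")
    expect_false(grepl("[*]", substr(aa, 1, nchar(aa) - 1)))
    expect_equal(substr(aa, nchar(aa), nchar(aa)), "*")
  }
  expect_setequal(strands_seen, c("+", "-"))
})

test_that("annotation is seed-deterministic and biotypes are diverse", {
  cfg <- small_config(seed = 5)
  a1 <- simulate_annotation(cfg)
  a2 <- simulate_annotation(cfg)
  expect_identical(a1$genes, a2$genes)
  expect_identical(as.character(a1$genome), as.character(a2$genome))
  expect_true("protein_coding" %in% a1$genes$biotype)
  expect_gt(length(intersect(unique(a1$genes$biotype),
                             c("lncRNA", "miRNA", "snRNA", "scaRNA", "tRNA"))), 1)
})

test_that("expression atlas is deterministic with planted overexpression", {
  cfg <- small_config(seed = 21)
  a1 <- simulate_expression_atlas(cfg)
  a2 <- simulate_expression_atlas(cfg)
  expect_identical(a1$expr, a2$expr)
  oe <- a1$overexpressed_gene_map[["mammary gland"]]
  cols <- a1$samples$tissue == "mammary gland"
  gap <- mean(a1$expr[oe[1], cols]) - mean(a1$expr[oe[1], !cols])
  expect_gt(gap, 1.5)
  expect_error(
    sim_config(samples_per_tissue = 1L), "samples_per_tissue")
})

test_that("PWM library round-trips through JASPAR text", {
  st <- get_small_study()
  lib <- st$pwms
  expect_true(all(vapply(lib, function(p)
    all(colSums(p$counts) == 100), TRUE)))
  tmp <- tempfile(fileext = ".jaspar")
  write_jaspar(lib, tmp)
  lib2 <- read_jaspar(tmp)
  expect_equal(names(lib2), names(lib))
  for (nm in names(lib))
    expect_equal(unname(lib2[[nm]]$counts), unname(lib[[nm]]$counts))
  expect_error(pwm("empty", matrix(numeric(0), 4, 0)), "zero-length")
})

test_that("dosage VCF round-trips", {
  st <- get_small_study()
  dos <- st$dosages
  tmp <- tempfile(fileext = ".vcf")
  sub <- dos
  sub$dosage <- dos$dosage[1:20, 1:30]
  sub$map <- dos$map[1:30, ]
  write_dosage_vcf(sub, tmp)
  back <- read_dosage_vcf(tmp)
  expect_equal(back$map$id, sub$map$id)
  expect_equal(back$dosage, sub$dosage, tolerance = 1e-3)
  expect_equal(back$map$r2, sub$map$r2, tolerance = 1e-5)
})
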