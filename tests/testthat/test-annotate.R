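# a hand-built two-gene annotation fixture with known coordinates
make_fixture_annot <- function() {
  # chromosome of 4000 bp
  set.seed(1234)
  seqv <- sample(c("A", "C", "G", "T"), 18000, replace = TRUE)
  # plus-strand gene: exon1 1001..1100 (5'UTR 1001..1040, CDS 1041..1100),
  # intron 1101..1400, exon2 1401..1520 (CDS 1401..1490, 3'UTR 1491..1520)
  cds1 <- c("ATG", "GGA", "CCT")                       # 9 bp warm-up
  ncod1 <- (1100 - 1041 + 1 - 9) / 3                   # remaining codons ex1
  ncod2 <- (1490 - 1401 + 1) / 3 - 1
  codons <- setdiff(apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                                      c("A","C","G","T")), 1, paste,
                          collapse = ""), c("TAA", "TAG", "TGA"))
  cds_seq <- paste(c(cds1, sample(codons, ncod1 + ncod2, replace = TRUE),
                     "TAA"), collapse = "")
  seqv[1041:1100] <- strsplit(substr(cds_seq, 1, 60), "")[[1]]
  seqv[1401:1490] <- strsplit(substr(cds_seq, 61, 150), "")[[1]]
  seqv[1101:1102] <- c("G", "T"); seqv[1399:1400] <- c("A", "G")
  genes_p <- data.frame(
    chrom = "1",
    start = c(1001, 1001, 1401, 1001, 1041, 1401, 1491),
    end = c(1520, 1100, 1520, 1040, 1100, 1490, 1520),
    strand = "+",
    type = c("gene", "exon", "exon", "five_prime_UTR", "CDS", "CDS",
             "three_prime_UTR"),
    gene_id = "GENEP", transcript_id = "TXP", biotype = "protein_coding",
    stringsAsFactors = FALSE)
  # minus-strand lncRNA: 15001..15400 single exon (windows clear of GENEP)
  genes_m <- data.frame(
    chrom = "1", start = c(15001, 15001), end = c(15400, 15400), strand = "-",
    type = c("gene", "exon"), gene_id = "GENEL", transcript_id = "TXL",
    biotype = "lncRNA", stringsAsFactors = FALSE)
  genome <- Biostrings::DNAStringSet(paste(seqv, collapse = ""))
  names(genome) <- "1"
  structure(list(genes = rbind(genes_p, genes_m), genome = genome),
            class = "gene_annotation")
}

variant_at <- function(annot, pos, alt = NULL) {
  ref <- as.character(Biostrings::subseq(annot$genome[["1"]], pos, pos))
  if (is.null(alt)) alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
  data.frame(chrom = "1", pos = pos, ref = ref, alt = alt,
             stringsAsFactors = FALSE)
}

test_that("coding consequences come from codon translation", {
  ann <- make_fixture_annot()
  # codon 2 of the CDS is GGA (Gly) at 1044..1046; GGA->AGA is missense (Arg)
  v <- variant_at(ann, 1044, "A")
  cc <- classify_variant(v, ann)
  expect_equal(cc$category, "missense")
  expect_equal(cc$protein_change, "p.G2R")
  # GGA->GGG is synonymous at codon position 3
  v2 <- variant_at(ann, 1046, "G")
  cc2 <- classify_variant(v2, ann)
  expect_equal(cc2$category, "synonymous")
  # indel with non-multiple-of-3 length difference is frameshift
  v3 <- variant_at(ann, 1050)
  v3$alt <- paste0(v3$ref, "AC")
  cc3 <- classify_variant(v3, ann)
  expect_equal(cc3$category, "frameshift")
})

test_that("UTRs, introns and splice classes follow strand-aware definitions", {
  ann <- make_fixture_annot()
  expect_equal(classify_variant(variant_at(ann, 1020), ann)$category, "5'UTR")
  expect_equal(classify_variant(variant_at(ann, 1500), ann)$category, "3'UTR")
  expect_equal(classify_variant(variant_at(ann, 1250), ann)$category, "intron")
  # + strand: intron bases 1-2 at its 3' end (1399, 1400) are acceptor
  expect_equal(classify_variant(variant_at(ann, 1399), ann)$category,
               "splice_acceptor")
  expect_equal(classify_variant(variant_at(ann, 1400), ann)$category,
               "splice_acceptor")
  # donor-side intron bases and 3-8 bp intronic are splice_region
  expect_equal(classify_variant(variant_at(ann, 1101), ann)$category,
               "splice_region")
  expect_equal(classify_variant(variant_at(ann, 1106), ann)$category,
               "splice_region")
  expect_equal(classify_variant(variant_at(ann, 1395), ann)$category,
               "splice_region")
})

test_that("upstream/downstream windows are strand-aware", {
  ann <- make_fixture_annot()
  # + strand gene at 1001..1520
  expect_equal(classify_variant(variant_at(ann, 900), ann)$category,
               "upstream")
  expect_equal(classify_variant(variant_at(ann, 1600), ann)$category,
               "downstream")
  # - strand lncRNA at 15001..15400: upstream lies at HIGHER coordinates
  expect_equal(classify_variant(variant_at(ann, 15500), ann)$category,
               "upstream")
  expect_equal(classify_variant(variant_at(ann, 14900), ann)$category,
               "downstream")
  expect_equal(classify_variant(variant_at(ann, 15100), ann)$category,
               "lncRNA")
})

test_that("non-overlapping variants are intergenic and REF mismatches error", {
  ann <- make_fixture_annot()
  # beyond every gene and window
  v <- variant_at(ann, 9000)
  expect_equal(classify_variant(v, ann)$category, "intergenic")
  vbad <- variant_at(ann, 1044)
  vbad$ref <- setdiff(c("A", "C", "G", "T"), vbad$ref)[1]
  expect_error(classify_variant(vbad, ann), "REF mismatch")
})

test_that("classifier agrees with a brute-force scan on simulated gene models", {
  st <- get_small_study()
  ann <- st$annotation
  set.seed(55)
  clen <- Biostrings::width(ann$genome)[1]
  pos <- sort(sample(seq(100, clen - 100), 120))
  ref <- vapply(pos, function(p)
    as.character(Biostrings::subseq(ann$genome[["1"]], p, p)), "")
  v <- data.frame(chrom = "1", pos = pos, ref = ref,
                  alt = vapply(ref, function(r)
                    setdiff(c("A", "C", "G", "T"), r)[1], ""),
                  stringsAsFactors = FALSE)
  calls <- classify_variant(v, ann)
  # brute force: coarse category by interval arithmetic per transcript
  g <- ann$genes
  brute_one <- function(p) {
    cats <- character(0)
    for (tid in unique(g$transcript_id)) {
      f <- g[g$transcript_id == tid, ]
      t_ <- f[f$type == "gene", ]
      if (as.character(t_$chrom) != "1") next
      if (p >= t_$start && p <= t_$end) {
        cds <- f[f$type == "CDS", ]
        ex <- f[f$type == "exon", ]
        in_cds <- nrow(cds) && any(p >= cds$start & p <= cds$end)
        in_ex <- any(p >= ex$start & p <= ex$end)
        if (in_cds) cats <- c(cats, "coding")
        else if (in_ex && t_$biotype != "protein_coding")
          cats <- c(cats, t_$biotype)
        else if (in_ex) cats <- c(cats, "utr_or_splice")
        else cats <- c(cats, "intronic")
      } else if ((t_$strand == "+" && p < t_$start && p >= t_$start - 5000) ||
                 (t_$strand == "-" && p > t_$end && p <= t_$end + 5000)) {
        cats <- c(cats, "upstream")
      } else if ((t_$strand == "+" && p > t_$end && p <= t_$end + 5000) ||
                 (t_$strand == "-" && p < t_$start && p >= t_$start - 5000)) {
        cats <- c(cats, "downstream")
      }
    }
    if (!length(cats)) "intergenic" else cats
  }
  coarse <- function(cat) {
    if (cat %in% c("missense", "synonymous", "frameshift")) "coding"
    else if (cat %in% c("5'UTR", "3'UTR")) "utr_or_splice"
    else if (cat %in% c("intron", "splice_acceptor")) "intronic"
    else if (cat == "splice_region") NA_character_  # straddles classes
    else cat
  }
  for (k in seq_along(pos)) {
    got <- calls$category[calls$pos == pos[k]]
    gc <- vapply(got, coarse, "")
    gc <- gc[!is.na(gc)]
    want <- brute_one(pos[k])
    # splice_region calls may legitimately map to either side; require the
    # remaining coarse classes to agree exactly as multisets
    if (length(gc))
      expect_true(all(gc %in% want), label = paste("pos", pos[k]))
    if (!length(got))
      fail(paste("no call at", pos[k]))
  }
})

test_that("every variant receives at least one call", {
  st <- get_small_study()
  ann <- st$annotation
  set.seed(66)
  pos <- sort(sample(seq(50, 5e5 - 50), 60))
  ref <- vapply(pos, function(p)
    as.character(Biostrings::subseq(ann$genome[["2"]], p, p)), "")
  v <- data.frame(chrom = "2", pos = pos, ref = ref,
                  alt = vapply(ref, function(r)
                    setdiff(c("A", "C", "G", "T"), r)[1], ""))
  calls <- classify_variant(v, ann)
  expect_true(all(v$pos %in% calls$pos))
})

test_that("rank_top_variants matches a full sort and truncates", {
  set.seed(8)
  n <- 100
  gw <- data.frame(id = paste0("v", 1:n), chrom = 1, pos = sample(1e6, n),
                   mlog10p = runif(n, 5, 40), r2 = runif(n), b = 0, se = 1,
                   freq = 0.5, stringsAsFactors = FALSE)
  region <- data.frame(n_variants = n)
  region$members <- I(list(gw$id))
  full <- rank_top_variants(region[1, ], gw, n)
  o <- order(-gw$mlog10p, -gw$r2, gw$pos)
  expect_equal(full$id, gw$id[o])
  expect_equal(rank_top_variants(region[1, ], gw, 10)$id, gw$id[o][1:10])
  expect_equal(nrow(rank_top_variants(region[1, ], gw, 500)), n)
  expect_equal(rank_top_variants(region[1, ], gw, 1)$id, gw$id[o][1])
})

test_that("annotation summary computes composition and aggregates", {
  calls <- data.frame(id = paste0("v", 1:4),
                      category = c("intergenic", "intron", "intron", "lncRNA"))
  s <- summarize_annotation(calls)
  expect_equal(s$by_category$pct[s$by_category$category == "intergenic"], 25)
  expect_equal(s$total_protein_coding, 2)
  expect_equal(s$total_ncRNA, 1)
  # empty input does not divide by zero
  s0 <- summarize_annotation(calls[0, ])
  expect_equal(s0$n_calls, 0)
  # planted composition recovered
  set.seed(3)
  cats <- sample(c("intron", "intergenic", "upstream"), 1000, replace = TRUE,
                 prob = c(0.5, 0.3, 0.2))
  s1 <- summarize_annotation(data.frame(id = seq_along(cats), category = cats))
  p_int <- s1$by_category$pct[s1$by_category$category == "intron"] / 100
  expect_lt(abs(p_int - 0.5), 3 * sqrt(0.25 / 1000) + 0.01)
})

test_that("positional candidates deduplicate by best rank and warn when empty", {
  gw <- data.frame(id = c("v1", "v2", "v3"), chrom = 1, pos = 1:3,
                   mlog10p = c(30, 20, 10), r2 = 1, stringsAsFactors = FALSE)
  region <- data.frame(region = 1, n_variants = 3)
  region$members <- I(list(c("v1", "v2", "v3")))
  calls <- data.frame(id = c("v1", "v2", "v3"),
                      category = c("intron", "intron", "upstream"),
                      gene_id = c("A", "A", "B"), stringsAsFactors = FALSE)
  expect_equal(positional_candidates(region[1, ], gw, calls), c("A", "B"))
  calls2 <- data.frame(id = "v1", category = "intergenic",
                       gene_id = NA_character_)
  expect_warning(out <- positional_candidates(region[1, ], gw, calls2),
                 "intergenic")
  expect_equal(out, character(0))
})
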