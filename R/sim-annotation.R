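#' Simulate gene models and a consistent genome sequence
#'
#' Generates `n_genes` genes spread over the configured chromosomes, on
#' both strands, with biotypes protein_coding (majority), lncRNA, miRNA,
#' snRNA, scaRNA and tRNA. Protein-coding transcripts have 2-4 exons, a
#' 5' UTR, a CDS whose length is divisible by 3, starts with ATG, ends
#' with a stop codon and contains no internal stop, and a 3' UTR; introns
#' carry canonical GT..AG splice dinucleotides. The chromosome sequences
#' are random background overwritten with each gene's designed sequence
#' (reverse-complemented for minus-strand genes), so gene-model
#' coordinates and FASTA agree by construction.
#'
#' @param config a [sim_config()].
#' @return list of class `gene_annotation` with `genes` (feature
#'   data.frame: `chrom`, `start`, `end` 1-based inclusive, `strand`,
#'   `type` in gene/exon/CDS/five_prime_UTR/three_prime_UTR, `gene_id`,
#'   `transcript_id`, `biotype`) and `genome` (a
#'   [Biostrings::DNAStringSet]).
#' @export
simulate_annotation <- function(config) {
  config <- validate_sim_config(config)
  set.seed(sim_subseed(config$seed, 5L))
  n_chr <- config$n_chromosomes
  clen <- as.integer(config$chrom_len)
  bases <- c("A", "C", "G", "T")
  chrom_seq <- lapply(seq_len(n_chr), function(i)
    sample(bases, clen, replace = TRUE))

  codons_no_stop <- setdiff(
    apply(expand.grid(bases, bases, bases), 1, paste, collapse = ""),
    c("TAA", "TAG", "TGA"))
  stops <- c("TAA", "TAG", "TGA")

  nb_types <- c("lncRNA", "miRNA", "snRNA", "scaRNA", "tRNA")
  n_genes <- config$n_genes
  biotype <- c(rep("protein_coding", ceiling(0.7 * n_genes)),
               sample(nb_types, n_genes - ceiling(0.7 * n_genes),
                      replace = TRUE))
  biotype <- sample(biotype)
  chrom_of <- sort(rep_len(seq_len(n_chr), n_genes))

  feats <- list()
  used_until <- rep(0L, n_chr)
  for (g in seq_len(n_genes)) {
    bt <- biotype[g]
    ch <- chrom_of[g]
    strand <- sample(c("+", "-"), 1L)
    gid <- sprintf("GENE%03d", g)
    tid <- sprintf("TX%03d", g)
    if (bt == "protein_coding") {
      n_ex <- sample(2:4, 1L)
      u5 <- sample(60:150, 1L)
      n_codon <- sample(80:200, 1L)
      cds_len <- 3L * n_codon
      u3 <- sample(100:250, 1L)
      tx_len <- u5 + cds_len + u3
      # split spliced transcript into exons
      cuts <- sort(sample(seq(30L, tx_len - 30L), n_ex - 1L))
      ex_len <- diff(c(0L, cuts, tx_len))
      while (any(ex_len < 20L)) {
        cuts <- sort(sample(seq(30L, tx_len - 30L), n_ex - 1L))
        ex_len <- diff(c(0L, cuts, tx_len))
      }
      introns <- sample(150:800, n_ex - 1L, replace = TRUE)
      tx_seq <- c(sample(bases, u5, replace = TRUE),
                  unlist(strsplit(c("ATG",
                                    sample(codons_no_stop, n_codon - 2L,
                                           replace = TRUE),
                                    sample(stops, 1L)), "")),
                  sample(bases, u3, replace = TRUE))
      stopifnot(length(tx_seq) == tx_len)
    } else {
      n_ex <- if (bt == "lncRNA") sample(1:2, 1L) else 1L
      tx_len <- switch(bt, lncRNA = sample(500:1500, 1L),
                       miRNA = 80L, snRNA = 150L, scaRNA = 270L, tRNA = 75L)
      if (n_ex == 2L) {
        cuts <- as.integer(round(tx_len / 2))
        ex_len <- c(cuts, tx_len - cuts)
        introns <- sample(150:500, 1L)
      } else { ex_len <- tx_len; introns <- integer(0) }
      tx_seq <- sample(bases, tx_len, replace = TRUE)
      u5 <- 0L; cds_len <- 0L; u3 <- 0L
    }
    gene_len <- sum(ex_len) + sum(introns)
    # genomic layout in transcript orientation (offset 0 = TSS)
    ex_start_t <- cumsum(c(0L, ex_len[-length(ex_len)] + introns))
    ex_end_t <- ex_start_t + ex_len - 1L
    # write gene sequence in transcript orientation
    gseq <- sample(bases, gene_len, replace = TRUE)
    for (e in seq_along(ex_len))
      gseq[(ex_start_t[e] + 1L):(ex_end_t[e] + 1L)] <-
        tx_seq[(cumsum(c(0L, ex_len))[e] + 1L):cumsum(ex_len)[e]]
    # canonical splice sites (GT..AG) in transcript orientation
    if (length(introns)) for (e in seq_len(length(ex_len) - 1L)) {
      i_start <- ex_end_t[e] + 1L       # 0-based offsets of intron
      i_end <- ex_start_t[e + 1L] - 1L
      gseq[i_start + 1L] <- "G"; gseq[i_start + 2L] <- "T"
      gseq[i_end] <- "A"; gseq[i_end + 1L] <- "G"
    }
    # place on chromosome with a gap
    gap <- sample(3000:12000, 1L)
    gstart <- used_until[ch] + gap
    gend <- gstart + gene_len - 1L
    if (gend > clen - 1000L) next  # chromosome full; skip remaining room
    used_until[ch] <- gend
    if (strand == "+") {
      chrom_seq[[ch]][gstart:gend] <- gseq
      t2g <- function(off) gstart + off       # offset 0-based -> 1-based pos
    } else {
      chrom_seq[[ch]][gstart:gend] <- rev(chartr("ACGT", "TGCA", gseq))
      t2g <- function(off) gend - off
    }
    rng <- function(o1, o2) {
      p <- sort(c(t2g(o1), t2g(o2)))
      c(start = p[1], end = p[2])
    }
    add <- function(type, o1, o2) {
      r <- rng(o1, o2)
      feats[[length(feats) + 1L]] <<- data.frame(
        chrom = ch, start = r[1], end = r[2], strand = strand, type = type,
        gene_id = gid, transcript_id = tid, biotype = bt,
        stringsAsFactors = FALSE)
    }
    add("gene", 0L, gene_len - 1L)
    for (e in seq_along(ex_len)) add("exon", ex_start_t[e], ex_end_t[e])
    if (bt == "protein_coding") {
      # map transcript (spliced) coordinates to genomic offsets
      sp2off <- function(sp) {   # sp: 1-based spliced coordinate
        cum <- cumsum(ex_len)
        e <- which(sp <= cum)[1L]
        prev <- if (e == 1L) 0L else cum[e - 1L]
        ex_start_t[e] + (sp - prev - 1L)
      }
      add_spliced <- function(type, sp1, sp2) {
        # emit one feature per exon chunk
        cum <- cumsum(ex_len)
        for (e in seq_along(ex_len)) {
          lo <- if (e == 1L) 1L else cum[e - 1L] + 1L
          hi <- cum[e]
          a <- max(sp1, lo); b <- min(sp2, hi)
          if (a <= b) add(type, sp2off(a), sp2off(b))
        }
      }
      if (u5 > 0L) add_spliced("five_prime_UTR", 1L, u5)
      add_spliced("CDS", u5 + 1L, u5 + cds_len)
      if (u3 > 0L) add_spliced("three_prime_UTR", u5 + cds_len + 1L,
                               u5 + cds_len + u3)
    }
  }
  genes <- do.call(rbind, feats)
  genome <- Biostrings::DNAStringSet(vapply(chrom_seq, paste, "",
                                            collapse = ""))
  names(genome) <- as.character(seq_len(n_chr))
  structure(list(genes = genes, genome = genome),
            class = "gene_annotation")
}

#' Write gene models as GFF3
#' @param annot a `gene_annotation` (or its `genes` data.frame).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(annot, path) {
  g <- if (inherits(annot, "gene_annotation")) annot$genes else annot
  attrs <- ifelse(g$type == "gene",
                  sprintf("ID=%s;biotype=%s", g$gene_id, g$biotype),
                  sprintf("ID=%s.%s;Parent=%s;biotype=%s", g$transcript_id,
                          g$type, g$gene_id, g$biotype))
  lines <- sprintf("%s\tmilkqtl\t%s\t%d\t%d\t.\t%s\t.\t%s",
                   g$chrom, g$type, g$start, g$end, g$strand, attrs)
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}
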