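#' Classify variants against gene models
#'
#' Assigns each variant one consequence category per overlapping
#' transcript, with within-transcript precedence
#' coding > splice > UTR > intron > upstream/downstream, and reports all
#' overlapping transcripts. Missense versus synonymous is decided by
#' translating the reference and alternate codons on the transcript's
#' strand; length-changing CDS variants whose length difference is not a
#' multiple of 3 are frameshift. Splice definitions follow the VEP
#' conventions: splice_acceptor = the last 2 intronic bases before an
#' exon (in transcription direction); splice_region = 1-3 bases into an
#' exon or 3-8 bases into an intron (donor bases 1-2 are reported as
#' splice_region since the vocabulary carries no donor class). Non-coding
#' transcripts label their exonic variants with the biotype (lncRNA,
#' miRNA, snRNA, scaRNA, tRNA). Upstream/downstream windows are
#' strand-aware (`window` bp, default 5 kb). Variants touching nothing are
#' intergenic.
#'
#' @param variants data.frame with `chrom`, `pos`, `ref`, `alt` (and
#'   optionally `id`).
#' @param annot a `gene_annotation` (genes + genome) from
#'   [simulate_annotation()] or equivalent.
#' @param window upstream/downstream window in bp.
#' @param check_ref error if a variant's REF disagrees with the genome.
#' @return data.frame of class `consequence_calls`: `id`, `chrom`, `pos`,
#'   `category`, `gene_id`, `transcript_id`, `protein_change` (NA unless
#'   coding). One row per (variant, category, gene) after deduplication;
#'   every variant gets at least one row.
#' @export
classify_variant <- function(variants, annot, window = 5000L,
                             check_ref = TRUE) {
  genes <- annot$genes
  genome <- annot$genome
  if (is.null(variants$id))
    variants$id <- sprintf("%s:%d", variants$chrom, variants$pos)
  variants$chrom <- as.character(variants$chrom)
  if (!all(variants$chrom %in% names(genome)))
    stop("variant chromosome absent from genome")
  if (check_ref) {
    for (k in seq_len(nrow(variants))) {
      v <- variants[k, ]
      obs <- as.character(Biostrings::subseq(
        genome[[v$chrom]], v$pos, v$pos + nchar(v$ref) - 1L))
      if (obs != v$ref)
        stop("REF mismatch at ", v$chrom, ":", v$pos,
             " (genome ", obs, ", variant ", v$ref, ")")
    }
  }
  tx <- genes[genes$type == "gene", , drop = FALSE]  # one tx per gene here
  vr <- GenomicRanges::GRanges(variants$chrom,
                               IRanges::IRanges(variants$pos, variants$pos))
  txr <- GenomicRanges::GRanges(tx$chrom,
                                IRanges::IRanges(tx$start, tx$end))
  wide <- GenomicRanges::resize(txr, GenomicRanges::width(txr) + 2L * window,
                                fix = "center")
  hits <- GenomicRanges::findOverlaps(vr, wide)
  out <- list()
  emit <- function(v, category, gene_id = NA_character_,
                   transcript_id = NA_character_, pchange = NA_character_) {
    out[[length(out) + 1L]] <<- data.frame(
      id = v$id, chrom = v$chrom, pos = v$pos, category = category,
      gene_id = gene_id, transcript_id = transcript_id,
      protein_change = pchange, stringsAsFactors = FALSE)
  }
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  for (k in seq_len(nrow(variants))) {
    v <- variants[k, ]
    tset <- sh[qh == k]
    called <- FALSE
    for (ti in tset) {
      t_ <- tx[ti, ]
      feats <- genes[genes$transcript_id == t_$transcript_id &
                     genes$type != "gene", , drop = FALSE]
      cat_ <- classify_one(v, t_, feats, genome, window)
      if (!is.na(cat_$category)) {
        emit(v, cat_$category, t_$gene_id, t_$transcript_id, cat_$pchange)
        called <- TRUE
      }
    }
    if (!called) emit(v, "intergenic")
  }
  res <- do.call(rbind, out)
  res <- unique(res[, c("id", "chrom", "pos", "category", "gene_id",
                        "transcript_id", "protein_change")])
  rownames(res) <- NULL
  class(res) <- c("consequence_calls", "data.frame")
  res
}

# one (variant, transcript) classification; returns list(category, pchange)
classify_one <- function(v, t_, feats, genome, window) {
  pos <- v$pos
  none <- list(category = NA_character_, pchange = NA_character_)
  inside <- pos >= t_$start && pos <= t_$end
  if (!inside) {
    # strand-aware flank: upstream is before the TSS
    if (t_$strand == "+") {
      if (pos < t_$start && pos >= t_$start - window)
        return(list(category = "upstream", pchange = NA_character_))
      if (pos > t_$end && pos <= t_$end + window)
        return(list(category = "downstream", pchange = NA_character_))
    } else {
      if (pos > t_$end && pos <= t_$end + window)
        return(list(category = "upstream", pchange = NA_character_))
      if (pos < t_$start && pos >= t_$start - window)
        return(list(category = "downstream", pchange = NA_character_))
    }
    return(none)
  }
  exons <- feats[feats$type == "exon", , drop = FALSE]
  exons <- exons[order(exons$start), , drop = FALSE]
  in_exon <- any(pos >= exons$start & pos <= exons$end)
  cds <- feats[feats$type == "CDS", , drop = FALSE]
  if (in_exon) {
    if (nrow(cds) && any(pos >= cds$start & pos <= cds$end))
      return(coding_consequence(v, t_, cds, genome))
    # splice_region: 1-3 bases into an exon measured from a splice junction
    if (nrow(exons) > 1L && exon_edge_dist(pos, exons) <= 2L)
      return(list(category = "splice_region", pchange = NA_character_))
    if (t_$biotype != "protein_coding")
      return(list(category = t_$biotype, pchange = NA_character_))
    utr5 <- feats[feats$type == "five_prime_UTR", , drop = FALSE]
    utr3 <- feats[feats$type == "three_prime_UTR", , drop = FALSE]
    if (nrow(utr5) && any(pos >= utr5$start & pos <= utr5$end))
      return(list(category = "5'UTR", pchange = NA_character_))
    if (nrow(utr3) && any(pos >= utr3$start & pos <= utr3$end))
      return(list(category = "3'UTR", pchange = NA_character_))
    return(list(category = "intron", pchange = NA_character_))  # unreachable
  }
  # intronic: locate the intron and measure strand-aware end distances
  ends <- exons$end[-nrow(exons)]; starts <- exons$start[-1L]
  for (ii in seq_along(ends)) {
    if (pos > ends[ii] && pos < starts[ii]) {
      d_left <- pos - ends[ii]            # bases into intron from left exon
      d_right <- starts[ii] - pos         # bases from right exon
      if (t_$strand == "+") { d_don <- d_left; d_acc <- d_right }
      else { d_don <- d_right; d_acc <- d_left }
      if (d_acc <= 2L)
        return(list(category = "splice_acceptor", pchange = NA_character_))
      if (d_don <= 8L || d_acc <= 8L)
        return(list(category = "splice_region", pchange = NA_character_))
      return(list(category = "intron", pchange = NA_character_))
    }
  }
  list(category = "intron", pchange = NA_character_)
}

# distance (0-based) from pos to the nearest internal exon boundary
exon_edge_dist <- function(pos, exons) {
  d <- Inf
  for (e in seq_len(nrow(exons))) {
    if (pos < exons$start[e] || pos > exons$end[e]) next
    if (e > 1L) d <- min(d, pos - exons$start[e])
    if (e < nrow(exons)) d <- min(d, exons$end[e] - pos)
  }
  d
}

# translate ref and alt codons for a CDS variant
coding_consequence <- function(v, t_, cds, genome) {
  if (nchar(v$ref) != nchar(v$alt)) {
    shift <- abs(nchar(v$ref) - nchar(v$alt)) %% 3L
    if (shift != 0L)
      return(list(category = "frameshift", pchange = NA_character_))
  }
  cds <- cds[order(cds$start), , drop = FALSE]
  pieces <- lapply(seq_len(nrow(cds)), function(i)
    as.character(Biostrings::subseq(genome[[as.character(cds$chrom[i])]],
                                    cds$start[i], cds$end[i])))
  cds_seq <- paste(unlist(pieces), collapse = "")
  # spliced CDS coordinate of the variant (plus-strand order first)
  off <- 0L; sp <- NA_integer_
  for (i in seq_len(nrow(cds))) {
    if (v$pos >= cds$start[i] && v$pos <= cds$end[i]) {
      sp <- off + (v$pos - cds$start[i] + 1L); break
    }
    off <- off + (cds$end[i] - cds$start[i] + 1L)
  }
  alt_seq <- cds_seq
  substr(alt_seq, sp, sp) <- v$alt
  if (t_$strand == "-") {
    cds_seq <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(cds_seq)))
    alt_seq <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(alt_seq)))
    sp <- nchar(cds_seq) - sp + 1L
  }
  codon_i <- (sp - 1L) %/% 3L + 1L
  ref_codon <- substr(cds_seq, 3L * codon_i - 2L, 3L * codon_i)
  alt_codon <- substr(alt_seq, 3L * codon_i - 2L, 3L * codon_i)
  aa_ref <- as.character(Biostrings::translate(
    Biostrings::DNAString(ref_codon), no.init.codon = TRUE))
  aa_alt <- as.character(Biostrings::translate(
    Biostrings::DNAString(alt_codon), no.init.codon = TRUE))
  if (aa_ref == aa_alt)
    return(list(category = "synonymous",
                pchange = sprintf("p.%s%d=", aa_ref, codon_i)))
  list(category = "missense",
       pchange = sprintf("p.%s%d%s", aa_ref, codon_i, aa_alt))
}

#' Rank the top variants of a QTL region
#'
#' Members sorted by -log10(P) descending, ties broken by higher
#' imputation R2 then lower position; the first `min(n, size)` returned.
#'
#' @param region one row of a `qtl_regions` table.
#' @param results the `gwas_result`.
#' @param n how many to return.
#' @return the ranked subset of `results`.
#' @export
rank_top_variants <- function(region, results, n) {
  m <- results[match(region$members[[1L]], results$id), , drop = FALSE]
  m <- m[top_variant_rank(m), , drop = FALSE]
  utils::head(m, n)
}

#' Summarize consequence-call composition
#'
#' Counts and percentages per category over a call set (each deduplicated
#' (variant, category, gene) call counted once), plus the aggregates
#' "total_protein_coding" (missense, synonymous, frameshift, splice
#' classes, UTRs, intron, up/downstream of coding genes) and
#' "total_ncRNA". When the calls carry a `source` column (chip/imputed),
#' the chip share is reported too.
#'
#' @param calls a `consequence_calls` data.frame (optionally with a
#'   `source` column merged in).
#' @return list with `by_category` (data.frame: category, n, pct),
#'   `n_calls`, `total_protein_coding`, `total_ncRNA`, and optionally
#'   `chip_share`.
#' @export
summarize_annotation <- function(calls) {
  if (!nrow(calls))
    return(list(by_category = data.frame(category = character(0),
                                         n = integer(0), pct = numeric(0)),
                n_calls = 0L, total_protein_coding = 0L, total_ncRNA = 0L))
  tab <- table(calls$category)
  by_cat <- data.frame(category = names(tab), n = as.integer(tab),
                       pct = 100 * as.integer(tab) / nrow(calls),
                       stringsAsFactors = FALSE)
  by_cat <- by_cat[order(-by_cat$n), , drop = FALSE]
  rownames(by_cat) <- NULL
  nc_cats <- c("lncRNA", "miRNA", "snRNA", "scaRNA", "tRNA")
  pc_cats <- c("missense", "synonymous", "frameshift", "splice_region",
               "splice_acceptor", "5'UTR", "3'UTR", "intron",
               "upstream", "downstream")
  out <- list(by_category = by_cat, n_calls = nrow(calls),
              total_protein_coding = sum(calls$category %in% pc_cats),
              total_ncRNA = sum(calls$category %in% nc_cats))
  if (!is.null(calls$source))
    out$chip_share <- mean(calls$source == "chip")
  out
}

#' Positional candidate genes of a QTL region
#'
#' Unique genes receiving any non-intergenic call from the region's
#' members, ordered by the best (lowest) rank of the member that hits
#' them. A fully intergenic region returns an empty vector with a warning.
#'
#' @param region one row of a `qtl_regions` table.
#' @param results the `gwas_result` (for ranking members).
#' @param calls `consequence_calls` covering the members.
#' @return character vector of gene ids.
#' @export
positional_candidates <- function(region, results, calls) {
  ranked <- rank_top_variants(region, results, n = region$n_variants)
  cc <- calls[calls$id %in% ranked$id & calls$category != "intergenic" &
              !is.na(calls$gene_id), , drop = FALSE]
  if (!nrow(cc)) {
    warning("region ", region$region %||% "", " has only intergenic calls")
    return(character(0))
  }
  cc$rank <- match(cc$id, ranked$id)
  cc <- cc[order(cc$rank), , drop = FALSE]
  unique(cc$gene_id)
}
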