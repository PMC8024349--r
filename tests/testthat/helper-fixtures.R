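# shared small fixtures, built once per test run

small_config <- function(seed = 101, ...) {
  sim_config(seed = seed, n_cows = 120, n_sires = 8, n_variants = 200,
             n_chromosomes = 2, chrom_len = 5e5, ld_block_len = 5e4,
             n_qtl = 2, n_genes = 25, n_traits = 2,
             h2_targets = c(0.5, 0.4),
             rg_matrix = matrix(c(1, .5, .5, 1), 2),
             records_per_cow = c(4L, 6L), ...)
}

# memoized small study shared across test files
.fixture_env <- new.env()
get_small_study <- function() {
  if (is.null(.fixture_env$study))
    .fixture_env$study <- simulate_study(small_config())
  .fixture_env$study
}

# brute-force recursive kinship oracle (Malecot): a(i,j) via parents
kinship_oracle <- function(ped) {
  idx <- seq_len(nrow(ped)); names(idx) <- ped$id
  si <- idx[ped$sire]; di <- idx[ped$dam]
  memo <- new.env()
  a <- function(i, j) {
    if (is.na(i) || is.na(j)) return(0)
    key <- paste(min(i, j), max(i, j))
    if (!is.null(memo[[key]])) return(memo[[key]])
    val <- if (i == j) 1 + 0.5 * a(si[i], di[i])
           else if (i < j) 0.5 * (a(i, si[j]) + a(i, di[j]))
           else 0.5 * (a(j, si[i]) + a(j, di[i]))
    memo[[key]] <- val
    val
  }
  # requires topological order (parents before offspring)
  n <- nrow(ped)
  M <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) for (j in i:n) M[i, j] <- M[j, i] <- a(i, j)
  M
}

# brute-force per-variant dense GLS oracle for the MLMA model
dense_gls_oracle <- function(y, X, x, V) {
  Vi <- solve(V)
  M <- cbind(X, x)
  XtVX <- t(M) %*% Vi %*% M
  b <- solve(XtVX, t(M) %*% Vi %*% y)
  se <- sqrt(diag(solve(XtVX)))
  k <- ncol(M)
  c(b = unname(b[k]), se = unname(se[k]))
}

# brute-force single-linkage chaining oracle
chain_oracle <- function(pos, max_gap) {
  pos <- sort(pos)
  g <- 1L; out <- integer(length(pos))
  out[1L] <- 1L
  for (i in seq_along(pos)[-1L]) {
    if (pos[i] - pos[i - 1L] >= max_gap) g <- g + 1L
    out[i] <- g
  }
  split(pos, out)
}

# brute-force PWM best-score oracle: enumerate all offsets and strands
scan_oracle <- function(seq, p) {
  x <- strsplit(seq, "")[[1]]
  L <- p$length
  rc <- function(s) chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  best <- -Inf
  for (o in 1:(length(x) - L + 1)) {
    win <- paste(x[o:(o + L - 1)], collapse = "")
    for (str in c("+", "-")) {
      w <- if (str == "+") win else rc(win)
      sc <- sum(vapply(seq_len(L), function(j)
        p$score[substr(w, j, j), j], 1))
      best <- max(best, sc)
    }
  }
  best
}

# full-category brute-force consequence oracle: plain nested loops and a
# local codon table, independent of the GRanges/Biostrings implementation
GENETIC_CODE_LOCAL <- c(
  TTT="F",TTC="F",TTA="L",TTG="L",CTT="L",CTC="L",CTA="L",CTG="L",
  ATT="I",ATC="I",ATA="I",ATG="M",GTT="V",GTC="V",GTA="V",GTG="V",
  TCT="S",TCC="S",TCA="S",TCG="S",CCT="P",CCC="P",CCA="P",CCG="P",
  ACT="T",ACC="T",ACA="T",ACG="T",GCT="A",GCC="A",GCA="A",GCG="A",
  TAT="Y",TAC="Y",TAA="*",TAG="*",CAT="H",CAC="H",CAA="Q",CAG="Q",
  AAT="N",AAC="N",AAA="K",AAG="K",GAT="D",GAC="D",GAA="E",GAG="E",
  TGT="C",TGC="C",TGA="*",TGG="W",CGT="R",CGC="R",CGA="R",CGG="R",
  AGT="S",AGC="S",AGA="R",AGG="R",GGT="G",GGC="G",GGA="G",GGG="G")

revcomp_str <- function(s)
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))

brute_classify <- function(v, gc, genome_str, window = 5000) {
  p <- v$pos
  cats <- character(0)
  for (tid in unique(gc$transcript_id)) {
    f <- gc[gc$transcript_id == tid, ]
    t_ <- f[f$type == "gene", ]
    plus <- t_$strand == "+"
    if (p < t_$start || p > t_$end) {
      if (plus && p < t_$start && p >= t_$start - window) cats <- c(cats, "upstream")
      else if (plus && p > t_$end && p <= t_$end + window) cats <- c(cats, "downstream")
      else if (!plus && p > t_$end && p <= t_$end + window) cats <- c(cats, "upstream")
      else if (!plus && p < t_$start && p >= t_$start - window) cats <- c(cats, "downstream")
      next
    }
    ex <- f[f$type == "exon", ]; ex <- ex[order(ex$start), ]
    cds <- f[f$type == "CDS", ]; cds <- cds[order(cds$start), ]
    in_cds <- nrow(cds) > 0 && any(p >= cds$start & p <= cds$end)
    in_ex <- any(p >= ex$start & p <= ex$end)
    if (in_cds) {
      # splice out the CDS, substitute the alt base, translate the codon
      cds_seq <- paste(vapply(seq_len(nrow(cds)), function(i)
        substr(genome_str, cds$start[i], cds$end[i]), ""), collapse = "")
      off <- 0; sp <- NA
      for (i in seq_len(nrow(cds))) {
        if (p >= cds$start[i] && p <= cds$end[i]) { sp <- off + p - cds$start[i] + 1; break }
        off <- off + cds$end[i] - cds$start[i] + 1
      }
      alt_seq <- cds_seq; substr(alt_seq, sp, sp) <- v$alt
      if (!plus) {
        cds_seq <- revcomp_str(cds_seq); alt_seq <- revcomp_str(alt_seq)
        sp <- nchar(cds_seq) - sp + 1
      }
      ci <- (sp - 1) %/% 3 + 1
      aa_r <- GENETIC_CODE_LOCAL[substr(cds_seq, 3 * ci - 2, 3 * ci)]
      aa_a <- GENETIC_CODE_LOCAL[substr(alt_seq, 3 * ci - 2, 3 * ci)]
      cats <- c(cats, if (identical(unname(aa_r), unname(aa_a))) "synonymous" else "missense")
      next
    }
    if (in_ex) {
      # distance from an internal splice junction, 0-based into the exon
      d <- Inf
      for (e in seq_len(nrow(ex))) {
        if (p < ex$start[e] || p > ex$end[e]) next
        if (e > 1) d <- min(d, p - ex$start[e])
        if (e < nrow(ex)) d <- min(d, ex$end[e] - p)
      }
      if (nrow(ex) > 1 && d <= 2) { cats <- c(cats, "splice_region"); next }
      if (t_$biotype != "protein_coding") { cats <- c(cats, t_$biotype); next }
      u5 <- f[f$type == "five_prime_UTR", ]
      u3 <- f[f$type == "three_prime_UTR", ]
      if (nrow(u5) && any(p >= u5$start & p <= u5$end)) cats <- c(cats, "5'UTR")
      else if (nrow(u3) && any(p >= u3$start & p <= u3$end)) cats <- c(cats, "3'UTR")
      else cats <- c(cats, "intron")
      next
    }
    # intronic
    done <- FALSE
    for (e in seq_len(nrow(ex) - 1)) {
      if (p > ex$end[e] && p < ex$start[e + 1]) {
        d_left <- p - ex$end[e]; d_right <- ex$start[e + 1] - p
        d_acc <- if (plus) d_right else d_left
        d_don <- if (plus) d_left else d_right
        if (d_acc <= 2) cats <- c(cats, "splice_acceptor")
        else if (d_don <= 8 || d_acc <= 8) cats <- c(cats, "splice_region")
        else cats <- c(cats, "intron")
        done <- TRUE; break
      }
    }
    if (!done) cats <- c(cats, "intron")
  }
  if (!length(cats)) "intergenic" else cats
}
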