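#' Write a dosage matrix as VCF 4.2 with a DS FORMAT field
#'
#' One sample column per cow; genotypes are stored as allele dosages in
#' the DS field (GT is set to `./.` since only dosages are simulated).
#' INFO carries MAF, DR2 (imputation R2) and SRC (chip/imputed).
#'
#' @param dosages a `dosage_matrix`.
#' @param path output file (plain text).
#' @return `path`, invisibly.
#' @export
write_dosage_vcf <- function(dosages, path) {
  map <- dosages$map
  D <- dosages$dosage
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=MAF,Number=1,Type=Float,Description=\"Minor allele frequency\">",
    "##INFO=<ID=DR2,Number=1,Type=Float,Description=\"Imputation R-squared\">",
    "##INFO=<ID=SRC,Number=1,Type=String,Description=\"chip or imputed\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage of ALT\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(D)), collapse = "\t")), con)
  for (v in seq_len(nrow(map))) {
    info <- sprintf("MAF=%.6g;DR2=%.6g;SRC=%s", map$maf[v], map$r2[v],
                    map$source[v])
    ds <- sprintf("./.:%.4g", D[, v])
    writeLines(paste(c(map$chrom[v], map$pos[v], map$id[v], map$ref[v],
                       map$alt[v], ".", "PASS", info, "GT:DS", ds),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a DS-field dosage VCF back into a dosage matrix
#'
#' @param path a VCF as written by [write_dosage_vcf()] (or any VCF whose
#'   FORMAT includes DS and whose INFO includes MAF and DR2).
#' @return a `dosage_matrix` (without LD-block bookkeeping).
#' @export
read_dosage_vcf <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#CHROM", lines)
  cols <- strsplit(lines[hdr], "\t")[[1L]]
  samples <- cols[-(1:9)]
  body <- lines[(hdr + 1L):length(lines)]
  body <- body[nzchar(body)]
  fields <- strsplit(body, "\t")
  get_info <- function(info, key) {
    m <- regmatches(info, regexpr(paste0(key, "=[^;]+"), info))
    if (!length(m)) return(NA)
    sub(paste0(key, "="), "", m)
  }
  n <- length(fields)
  map <- data.frame(
    id = vapply(fields, `[[`, "", 3L),
    chrom = as.integer(vapply(fields, `[[`, "", 1L)),
    pos = as.numeric(vapply(fields, `[[`, "", 2L)),
    ref = vapply(fields, `[[`, "", 4L),
    alt = vapply(fields, `[[`, "", 5L),
    stringsAsFactors = FALSE)
  info <- vapply(fields, `[[`, "", 8L)
  map$maf <- as.numeric(vapply(info, get_info, "", "MAF"))
  map$r2 <- as.numeric(vapply(info, get_info, "", "DR2"))
  map$source <- vapply(info, get_info, "", "SRC")
  fmt <- strsplit(vapply(fields, `[[`, "", 9L), ":")
  D <- matrix(NA_real_, length(samples), n,
              dimnames = list(samples, map$id))
  for (v in seq_len(n)) {
    ds_i <- match("DS", fmt[[v]])
    gt <- strsplit(fields[[v]][-(1:9)], ":")
    D[, v] <- as.numeric(vapply(gt, `[[`, "", ds_i))
  }
  map$alt_freq <- colMeans(D) / 2
  out <- list(dosage = D, map = map)
  class(out) <- "dosage_matrix"
  out
}

#' Write every simulated input of a study to a directory
#'
#' Emits the documented plain-text interchange formats: phenotypes,
#' pedigree and atlas as TSV, dosages as VCF 4.2 (DS field), gene models
#' as GFF3, the genome as FASTA, PWMs as JASPAR text, and the ground
#' truth as JSON.
#'
#' @param study a [simulate_study()] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(x) file.path(dir, x)
  utils::write.table(study$pedigree, fp("pedigree.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(study$test_days, fp("test_days.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_dosage_vcf(study$dosages, fp("dosages.vcf"))
  write_gff3(study$annotation, fp("genes.gff3"))
  Biostrings::writeXStringSet(study$annotation$genome, fp("genome.fa"))
  write_jaspar(study$pwms, fp("pwms.jaspar"))
  utils::write.table(
    data.frame(gene = rownames(study$atlas$expr), study$atlas$expr,
               check.names = FALSE),
    fp("atlas_expr.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(study$atlas$samples, fp("atlas_samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- attr(study$test_days, "truth")
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    gt <- list(qtl = truth$qtl, varcomps = lapply(truth$varcomps, unclass),
               overexpressed_gene_map = study$atlas$overexpressed_gene_map)
    jsonlite::write_json(gt, fp("ground_truth.json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(dir)
}
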