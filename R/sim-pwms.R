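#' Simulate a library of transcription-factor PWMs
#'
#' Each motif is a 4 x L count matrix (rows A, C, G, T; columns sum to a
#' fixed count total of 100) built around a random consensus: the
#' consensus base receives most of the counts, the rest are spread over
#' the other bases, with a few degenerate positions per motif. Motif
#' lengths are drawn in \[6, 20\].
#'
#' @param config a [sim_config()]; uses `n_pwms` and `seed`.
#' @param min_len,max_len motif length bounds.
#' @return object of class `pwm_library`: a named list of [pwm()] objects.
#' @export
simulate_pwms <- function(config, min_len = 6L, max_len = 12L) {
  config <- validate_sim_config(config)
  set.seed(sim_subseed(config$seed, 7L))
  bases <- c("A", "C", "G", "T")
  lib <- list()
  for (k in seq_len(config$n_pwms)) {
    L <- sample(min_len:max_len, 1L)
    cons <- sample(bases, L, replace = TRUE)
    M <- matrix(2L, 4L, L, dimnames = list(bases, NULL))
    for (j in seq_len(L)) M[cons[j], j] <- 94L
    # degenerate positions: split counts between two bases
    for (j in sample(seq_len(L), max(1L, L %/% 4L))) {
      other <- sample(setdiff(bases, cons[j]), 1L)
      M[cons[j], j] <- 64L; M[other, j] <- 32L
    }
    name <- sprintf("TF%03d", k)
    lib[[name]] <- pwm(name, M)
  }
  class(lib) <- "pwm_library"
  lib
}

#' Construct a position weight matrix object
#'
#' @param name TF/motif name.
#' @param counts 4 x L non-negative count matrix, rows named A, C, G, T.
#' @param background background base frequencies (sums to 1).
#' @param pseudocount total pseudocount, split by background frequency
#'   (the common JASPAR-tool convention, default 0.8).
#' @return object of class `pwm` with the count matrix, the log2-odds
#'   score matrix, background and pseudocount.
#' @export
pwm <- function(name, counts, background = rep(0.25, 4), pseudocount = 0.8) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 1L) stop("zero-length motif")
  if (nrow(counts) != 4L) stop("count matrix must have 4 rows (A,C,G,T)")
  if (any(counts < 0)) stop("negative counts")
  if (abs(sum(background) - 1) > 1e-8) stop("background must sum to 1")
  rownames(counts) <- c("A", "C", "G", "T")
  names(background) <- c("A", "C", "G", "T")
  tot <- colSums(counts)
  freq <- sweep(counts + pseudocount * background, 2, tot + pseudocount, "/")
  score <- log2(freq / background)
  structure(list(name = name, counts = counts, background = background,
                 pseudocount = pseudocount, score = score,
                 length = ncol(counts)), class = "pwm")
}

#' Write a PWM library in JASPAR text format
#'
#' @param lib a `pwm_library` (or list of [pwm()]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_jaspar <- function(lib, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in lib) {
    writeLines(paste0(">", p$name), con)
    for (b in c("A", "C", "G", "T"))
      writeLines(sprintf("%s  [ %s ]", b,
                         paste(format(p$counts[b, ]), collapse = " ")), con)
  }
  invisible(path)
}

#' Read a PWM library from JASPAR text format
#'
#' @param path file written by [write_jaspar()] or any JASPAR-2016-style
#'   text file (`>name` header, four bracketed count rows).
#' @param background,pseudocount passed to [pwm()].
#' @return a `pwm_library`.
#' @export
read_jaspar <- function(path, background = rep(0.25, 4), pseudocount = 0.8) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  heads <- grep("^>", lines)
  lib <- list()
  for (h in heads) {
    name <- sub("^>\\s*", "", lines[h])
    name <- strsplit(name, "\\s+")[[1L]][1L]
    rows <- lines[(h + 1L):(h + 4L)]
    parsed <- lapply(rows, function(r) {
      s <- sub("^\\s*[ACGTacgt]", "", r)
      as.numeric(regmatches(s, gregexpr("-?[0-9.]+", s))[[1L]])
    })
    if (length(unique(lengths(parsed))) != 1L)
      stop("ragged count rows for motif ", name)
    counts <- do.call(rbind, parsed)
    lib[[name]] <- pwm(name, counts, background, pseudocount)
  }
  class(lib) <- "pwm_library"
  lib
}
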