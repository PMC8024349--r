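#' Additive relationship matrix by the tabular method
#'
#' Computes Wright's numerator relationship matrix **A** from a trio
#' pedigree. Animals are topologically sorted first; unknown parents are
#' treated as unrelated, non-inbred founders. The diagonal is
#' 1 + F (the inbreeding coefficient).
#'
#' Dense O(n^2) storage: intended for pedigrees up to a few thousand
#' animals. The REML machinery never forms A; it uses the sparse inverse
#' from [a_inverse()].
#'
#' @param ped data.frame with columns `id`, `sire`, `dam`.
#' @return symmetric matrix with dimnames = animal ids (original order).
#' @export
build_A <- function(ped) {
  sp <- pedigree_sort(ped)
  n <- nrow(sp)
  idx <- seq_len(n); names(idx) <- sp$id
  si <- idx[sp$sire]; di <- idx[sp$dam]
  A <- matrix(0, n, n, dimnames = list(sp$id, sp$id))
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      row <- numeric(i - 1L)
      if (!is.na(s)) row <- row + 0.5 * A[j, s]
      if (!is.na(d)) row <- row + 0.5 * A[j, d]
      A[j, i] <- row
      A[i, j] <- row
    }
    A[i, i] <- 1 + if (!is.na(s) && !is.na(d)) 0.5 * A[s, d] else 0
  }
  A[ped$id, ped$id]
}

#' Inbreeding coefficients by the Meuwissen-Luo algorithm
#'
#' O(n x pedigree-depth^2); avoids forming A.
#'
#' @param ped data.frame with columns `id`, `sire`, `dam`.
#' @return named numeric vector of F, in the input order.
#' @export
inbreeding_coefs <- function(ped) {
  sp <- pedigree_sort(ped)
  n <- nrow(sp)
  idx <- seq_len(n); names(idx) <- sp$id
  si <- idx[sp$sire]; di <- idx[sp$dam]
  si[is.na(si)] <- 0L; di[is.na(di)] <- 0L
  f <- numeric(n)
  # per-animal Mendelian-sampling diagonal d_i, filled as we go
  dvec <- numeric(n)
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    fs <- if (s > 0L) f[s] else -1
    fd <- if (d > 0L) f[d] else -1
    dvec[i] <- 0.5 - 0.25 * (fs + fd)
    if (s == 0L || d == 0L) { f[i] <- 0; next }
    # accumulate L-row of animal i over its ancestors
    L <- numeric(i)
    L[i] <- 1
    fi <- 0
    for (j in i:1) {
      if (L[j] == 0) next
      sj <- si[j]; dj <- di[j]
      if (sj > 0L) L[sj] <- L[sj] + 0.5 * L[j]
      if (dj > 0L) L[dj] <- L[dj] + 0.5 * L[j]
      fi <- fi + L[j]^2 * dvec[j]
    }
    f[i] <- fi - 1
  }
  names(f) <- sp$id
  f[ped$id]
}

#' Sparse inverse of the additive relationship matrix
#'
#' Henderson's rules with inbreeding: A^-1 = sum over animals of
#' q_i q_i' / d_i where q_i has 1 at the animal and -1/2 at its known
#' parents, and d_i is the Mendelian-sampling variance
#' 0.5 - 0.25 (F_s + F_d) (with F = -1 for unknown parents).
#'
#' @param ped data.frame with columns `id`, `sire`, `dam`.
#' @return a sparse symmetric `Matrix::dsCMatrix` with animal-id dimnames,
#'   in the input order.
#' @export
a_inverse <- function(ped) {
  f <- inbreeding_coefs(ped)
  n <- nrow(ped)
  idx <- seq_len(n); names(idx) <- ped$id
  si <- idx[ped$sire]; di <- idx[ped$dam]
  fs <- ifelse(is.na(si), -1, f[ped$sire])
  fd <- ifelse(is.na(di), -1, f[ped$dam])
  dinv <- 1 / (0.5 - 0.25 * (fs + fd))
  i_self <- seq_len(n)
  hs <- !is.na(si); hd <- !is.na(di)
  ii <- c(i_self, i_self[hs], si[hs], i_self[hd], di[hd],
          si[hs & hd], di[hs & hd])
  jj <- c(i_self, si[hs], i_self[hs], di[hd], i_self[hd],
          di[hs & hd], si[hs & hd])
  xx <- c(dinv,
          -0.5 * dinv[hs], -0.5 * dinv[hs],
          -0.5 * dinv[hd], -0.5 * dinv[hd],
          0.25 * dinv[hs & hd], 0.25 * dinv[hs & hd])
  # parent-parent and parent self terms: q_i outer adds 0.25/d to each known
  # parent diagonal as well
  ii <- c(ii, si[hs], di[hd])
  jj <- c(jj, si[hs], di[hd])
  xx <- c(xx, 0.25 * dinv[hs], 0.25 * dinv[hd])
  Ainv <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                               dimnames = list(ped$id, ped$id))
  Matrix::forceSymmetric((Ainv + Matrix::t(Ainv)) / 2)
}
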