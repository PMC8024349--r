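#' Specify a repeatability animal model for a trait pair
#'
#' The model for each trait is
#'   y = X beta + Z a + W p + e
#' with fixed effects beta (by default the herd x test-day combination,
#' lactation stage and season of calving), additive genetic effects
#' a ~ N(0, A kron G0) with A the pedigree numerator relationship matrix,
#' permanent-environment effects p ~ N(0, I kron P0) for repeated records
#' on the same cow, and residuals e ~ N(0, I kron R0). G0, P0, R0 are
#' 2 x 2 (co)variance matrices for the trait pair.
#'
#' @param traits character(2): trait column names in the record table. The
#'   same trait twice requests the univariate model (expanded on return
#'   with rg = 1).
#' @param fixed character: fixed-effect factor columns.
#' @param pedigree trio pedigree data.frame (`id`, `sire`, `dam`).
#' @param pool_min fixed-factor levels observed fewer than `pool_min` times
#'   are absorbed into a pooled level to keep the design estimable.
#' @return object of class `repeatability_model`.
#' @export
repeatability_model <- function(traits, pedigree,
                                fixed = c("htd", "stage", "season"),
                                pool_min = 2L) {
  stopifnot(length(traits) == 2L)
  structure(list(traits = traits, fixed = fixed, pedigree = pedigree,
                 pool_min = as.integer(pool_min)),
            class = "repeatability_model")
}

# pooled, checked sparse fixed-design matrix; errors on aliased columns
build_fixed_design <- function(records, fixed, pool_min) {
  df <- records[fixed]
  for (j in seq_along(df)) {
    v <- as.character(df[[j]])
    tab <- table(v)
    rare <- names(tab)[tab < pool_min]
    if (length(rare)) v[v %in% rare] <- ".pooled"
    df[[j]] <- factor(v)
  }
  form <- stats::as.formula(paste("~", paste(fixed, collapse = " + ")))
  X <- Matrix::sparse.model.matrix(form, df)
  XtX <- as.matrix(Matrix::crossprod(X))
  qr_ <- qr(XtX)
  if (qr_$rank < ncol(X)) {
    aliased <- colnames(X)[qr_$pivot[(qr_$rank + 1L):ncol(X)]]
    # silently drop structurally aliased contrasts only if they are exact
    X <- X[, setdiff(colnames(X), aliased), drop = FALSE]
    XtX2 <- as.matrix(Matrix::crossprod(X))
    if (qr(XtX2)$rank < ncol(X))
      stop("singular fixed-effect design; aliased levels: ",
           paste(aliased, collapse = ", "))
    attr(X, "aliased") <- aliased
  }
  X
}

# Cholesky-parameterized 2x2 SPD matrix: th = (l11, l21, l22),
# L = [exp(l11) 0; l21 exp(l22)]
th2cov <- function(th) {
  L <- matrix(c(exp(th[1]), th[2], 0, exp(th[3])), 2, 2)
  L %*% t(L)
}
cov2th <- function(S) {
  L <- t(chol(S))
  c(log(L[1, 1]), L[2, 1], log(L[2, 2]))
}

#' Fit the bivariate repeatability animal model by REML
#'
#' Maximizes the restricted log-likelihood of the trait-pair model over the
#' nine (co)variance parameters of G0, P0 and R0, each parameterized by its
#' Cholesky factor to enforce positive semi-definiteness. The likelihood is
#' evaluated exactly through the sparse mixed-model equations
#' (-2 logLr = log|R| + log|G| + log|C| + y'Py up to a constant) with the
#' pedigree entering as the sparse A-inverse; optimization is quasi-Newton
#' (L-BFGS-B) from moment-based starting values, with diagonal parameters
#' bounded below at a small positive floor (1e-8 x phenotypic variance).
#' Approximate standard errors of h2 and rg come from the inverse
#' average-information matrix evaluated at the optimum.
#'
#' @param records a test-day table (long rows, trait columns).
#' @param model a [repeatability_model()].
#' @param tol relative restricted-log-likelihood convergence tolerance.
#' @param max_iter maximum optimizer iterations.
#' @param verbose print optimizer trace.
#' @return object of class `varcomp_fit` with elements `G0`, `P0`, `R0`,
#'   `h2`, `rg`, `se_h2`, `se_rg`, `loglik`, `converged`, `boundary`,
#'   `n_iter`, BLUE/BLUP solutions (`beta`, `a`, `p`) per trait, and the
#'   design bookkeeping needed by [compute_yield_deviations()].
#' @export
fit_bivariate_reml <- function(records, model, tol = 1e-6, max_iter = 200L,
                               verbose = FALSE) {
  stopifnot(inherits(model, "repeatability_model"))
  traits <- model$traits
  univariate <- traits[1] == traits[2]

  y1 <- records[[traits[1]]]
  ok <- is.finite(y1)
  if (!univariate) ok <- ok & is.finite(records[[traits[2]]])
  rec <- records[ok, , drop = FALSE]
  nrec <- nrow(rec)
  if (nrec < 10L) stop("too few complete records for REML")

  ped <- pedigree_sort(model$pedigree[, c("id", "sire", "dam")])
  anim_ids <- ped$id
  if (!all(rec$cow %in% anim_ids))
    stop("records reference cows absent from the pedigree")
  cows <- sort(unique(rec$cow))
  n_anim <- length(anim_ids); n_cow <- length(cows)

  X <- build_fixed_design(rec, model$fixed, model$pool_min)
  pfix <- ncol(X)
  Z <- Matrix::sparseMatrix(i = seq_len(nrec),
                            j = match(rec$cow, anim_ids),
                            x = 1, dims = c(nrec, n_anim))
  W <- Matrix::sparseMatrix(i = seq_len(nrec),
                            j = match(rec$cow, cows),
                            x = 1, dims = c(nrec, n_cow))
  Wall <- cbind(X, Z, W)
  S <- Matrix::crossprod(Wall)
  ptot <- ncol(Wall)
  a_off <- pfix; p_off <- pfix + n_anim

  Ainv <- a_inverse(ped)
  Tr <- as(as(Ainv, "generalMatrix"), "TsparseMatrix")
  ai_i <- Tr@i + 1L; ai_j <- Tr@j + 1L; ai_x <- Tr@x

  nt <- if (univariate) 1L else 2L
  Y <- if (univariate) cbind(rec[[traits[1]]])
       else cbind(rec[[traits[1]]], rec[[traits[2]]])
  sy <- Matrix::crossprod(Wall, Y)           # ptot x nt
  yy <- crossprod(Y)                          # nt x nt

  # Precompute the sparse pattern of the coefficient matrix
  #   C = sum over (t1 <= t2) trait blocks of
  #       R0inv[t1,t2] * S  +  G0inv[t1,t2] * Ainv  +  P0inv[t1,t2] * I_cow
  # once, as an upper-triangle dsCMatrix; per evaluation only the numeric
  # values are refreshed and the cached symbolic factorization reused.
  Sg <- as(as(S, "generalMatrix"), "TsparseMatrix")
  si <- Sg@i + 1L; sj <- Sg@j + 1L; sx <- Sg@x
  N <- nt * ptot
  blk <- list(); comp <- character(0)
  add_blk <- function(i, j, x, t1, t2, kind) {
    o1 <- (t1 - 1L) * ptot; o2 <- (t2 - 1L) * ptot
    gi <- o1 + i; gj <- o2 + j
    keep <- if (t1 == t2) gi <= gj else rep(TRUE, length(gi))
    blk[[length(blk) + 1L]] <<- list(i = gi[keep], j = gj[keep], x = x[keep])
    comp[length(comp) + 1L] <<- paste0(kind, t1, t2)
  }
  for (t1 in seq_len(nt)) for (t2 in t1:nt) {
    if (t1 == t2) {
      ku <- si <= sj
      add_blk(si[ku], sj[ku], sx[ku], t1, t2, "R")
      ku <- ai_i <= ai_j
      add_blk(a_off + ai_i[ku], a_off + ai_j[ku], ai_x[ku], t1, t2, "G")
      add_blk(p_off + seq_len(n_cow), p_off + seq_len(n_cow),
              rep(1, n_cow), t1, t2, "P")
    } else {
      add_blk(si, sj, sx, t1, t2, "R")
      add_blk(a_off + ai_i, a_off + ai_j, ai_x, t1, t2, "G")
      add_blk(p_off + seq_len(n_cow), p_off + seq_len(n_cow),
              rep(1, n_cow), t1, t2, "P")
    }
  }
  all_i <- unlist(lapply(blk, `[[`, "i"))
  all_j <- unlist(lapply(blk, `[[`, "j"))
  all_x <- unlist(lapply(blk, `[[`, "x"))
  key <- all_i + (all_j - 1) * N
  Cup <- Matrix::sparseMatrix(i = all_i, j = all_j, x = all_x,
                              dims = c(N, N))
  uk <- sort(unique(key))
  stopifnot(length(uk) == length(Cup@x))
  pos <- match(key, uk)
  Csym <- Matrix::forceSymmetric(Cup, uplo = "U")
  nnzC <- length(Csym@x)
  blk_pos <- split(pos, rep(seq_along(blk), vapply(blk, function(b) length(b$i), 1L)))
  blk_x <- lapply(blk, `[[`, "x")

  assemble <- function(R0i, G0i, P0i) {
    xv <- numeric(nnzC)
    for (k in seq_along(blk)) {
      kind <- substr(comp[k], 1, 1)
      t1 <- as.integer(substr(comp[k], 2, 2)); t2 <- as.integer(substr(comp[k], 3, 3))
      cf <- switch(kind, R = R0i[t1, t2], G = G0i[t1, t2], P = P0i[t1, t2])
      p <- blk_pos[[k]]
      xv[p] <- xv[p] + cf * blk_x[[k]]
    }
    Csym@x <- xv
    Csym
  }

  floor_var <- 1e-8 * mean(diag(yy) / nrec)
  state <- new.env(parent = emptyenv())
  state$symb <- NULL

  negll <- function(th) {
    if (univariate) {
      G0 <- matrix(exp(th[1])^2); P0 <- matrix(exp(th[2])^2)
      R0 <- matrix(exp(th[3])^2)
    } else {
      G0 <- th2cov(th[1:3]); P0 <- th2cov(th[4:6]); R0 <- th2cov(th[7:9])
    }
    G0i <- solve(G0); P0i <- solve(P0); R0i <- solve(R0)
    C <- assemble(R0i, G0i, P0i)
    ch <- tryCatch({
      if (is.null(state$symb)) {
        state$symb <- Matrix::Cholesky(C, LDL = FALSE, super = TRUE)
        state$symb
      } else Matrix::update(state$symb, C)
    }, error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    r <- as.numeric(sy %*% R0i)               # stacks trait-major columns
    sol <- as.numeric(Matrix::solve(ch, r))
    yRy <- sum(R0i * yy)
    yPy <- yRy - sum(sol * r)
    ldC <- 2 * as.numeric(Matrix::determinant(ch, sqrt = TRUE)$modulus)
    v <- 0.5 * (nrec * determinant(R0)$modulus +
                n_anim * determinant(G0)$modulus +
                n_cow * determinant(P0)$modulus + ldC + yPy)
    state$last <- list(th = th, sol = sol, ch = ch, G0 = G0, P0 = P0,
                       R0 = R0, G0i = G0i, P0i = P0i, R0i = R0i, yPy = yPy)
    as.numeric(v)
  }

  # moment-based starting values: within-cow covariance -> R0; between-cow
  # cow-mean covariance split between G0 and P0
  Yc <- Y - matrix(colMeans(Y), nrec, nt, byrow = TRUE)
  cow_f <- factor(rec$cow, levels = cows)
  cm <- apply(Yc, 2, function(v) tapply(v, cow_f, mean))
  cm <- matrix(cm, ncol = nt)
  nrep <- as.numeric(table(cow_f))
  Rw <- matrix(0, nt, nt)
  for (t1 in seq_len(nt)) for (t2 in seq_len(nt)) {
    d1 <- Yc[, t1] - cm[match(rec$cow, cows), t1]
    d2 <- Yc[, t2] - cm[match(rec$cow, cows), t2]
    Rw[t1, t2] <- sum(d1 * d2) / (nrec - n_cow)
  }
  B <- stats::cov(cm) - Rw * mean(1 / nrep)
  B <- B + diag(max(1e-3, 1e-2 * mean(diag(Rw))), nt)
  G0s <- 0.7 * B; P0s <- 0.3 * B
  mk_pd <- function(M) {
    ev <- eigen((M + t(M)) / 2, symmetric = TRUE)
    ev$vectors %*% diag(pmax(ev$values, 1e-4), nt) %*% t(ev$vectors)
  }
  if (univariate) {
    th0 <- 0.5 * log(pmax(c(G0s[1, 1], P0s[1, 1], Rw[1, 1]), 1e-4))
    lower <- rep(0.5 * log(floor_var), 3)
    upper <- rep(Inf, 3)
  } else {
    th0 <- c(cov2th(mk_pd(G0s)), cov2th(mk_pd(P0s)), cov2th(mk_pd(Rw)))
    lower <- rep(-Inf, 9); lower[c(1, 3, 4, 6, 7, 9)] <- 0.5 * log(floor_var)
    upper <- rep(Inf, 9)
  }

  opt <- stats::optim(th0, negll, method = "L-BFGS-B",
                      lower = lower, upper = upper,
                      control = list(maxit = max_iter, factr = tol / 1e-15,
                                     trace = if (verbose) 1L else 0L))
  val <- negll(opt$par)                      # refresh state at optimum
  st <- state$last
  G0 <- st$G0; P0 <- st$P0; R0 <- st$R0
  boundary <- any(abs(opt$par - lower) < 1e-6)
  if (univariate) {
    G0 <- matrix(G0[1, 1], 2, 2); P0 <- matrix(P0[1, 1], 2, 2)
    R0 <- matrix(R0[1, 1], 2, 2)
  }
  vp <- diag(G0 + P0 + R0)
  h2 <- diag(G0) / vp
  rg <- G0[1, 2] / sqrt(G0[1, 1] * G0[2, 2])

  # unpack solutions per trait
  sol <- matrix(st$sol, ncol = nt)
  beta <- sol[seq_len(pfix), , drop = FALSE]
  rownames(beta) <- colnames(X)
  a_bl <- sol[a_off + seq_len(n_anim), , drop = FALSE]; rownames(a_bl) <- anim_ids
  p_bl <- sol[p_off + seq_len(n_cow), , drop = FALSE]; rownames(p_bl) <- cows

  se <- tryCatch(
    reml_ai_se(st, Wall, Y, Z, W, Ainv, G0, P0, R0, h2, rg, univariate),
    error = function(e) list(h2 = rep(NA_real_, 2), rg = NA_real_))

  out <- list(traits = traits, G0 = G0, P0 = P0, R0 = R0,
              h2 = if (univariate) rep(h2[1], 2) else h2,
              rg = if (univariate) 1 else rg,
              se_h2 = se$h2, se_rg = if (univariate) 0 else se$rg,
              loglik = -val, converged = opt$convergence == 0L,
              boundary = boundary, n_iter = opt$counts[["function"]],
              beta = beta, a = a_bl, p = p_bl,
              design = list(X = X, fixed = model$fixed,
                            pool_min = model$pool_min,
                            records_used = which(ok),
                            cow = rec$cow, cows = cows,
                            Y = Y, univariate = univariate))
  class(out) <- "varcomp_fit"
  out
}

# average-information SEs for h2 and rg via the delta method
reml_ai_se <- function(st, Wall, Y, Z, W, Ainv, G0, P0, R0, h2, rg,
                       univariate) {
  nt <- ncol(Y); nrec <- nrow(Y)
  R0i <- st$R0i
  ptot <- ncol(Wall)
  sol <- matrix(st$sol, ncol = nt)
  E <- Y - as.matrix(Wall %*% sol)            # residuals per trait
  Py <- E %*% R0i                             # record-space P y per trait
  chA <- Matrix::Cholesky(Ainv, LDL = FALSE)
  ZtPy <- as.matrix(Matrix::crossprod(Z, Py))
  AZtPy <- as.matrix(Matrix::solve(chA, ZtPy))
  ZAZPy <- as.matrix(Z %*% AZtPy)
  WWtPy <- as.matrix(W %*% Matrix::crossprod(W, Py))

  sym_pairs <- if (nt == 1) list(c(1, 1)) else list(c(1, 1), c(1, 2), c(2, 2))
  fs <- list()
  mk_f <- function(base, kl) {
    f <- matrix(0, nrec, nt)
    k <- kl[1]; l <- kl[2]
    f[, k] <- f[, k] + base[, l]
    if (k != l) f[, l] <- f[, l] + base[, k]
    f
  }
  for (kl in sym_pairs) fs[[length(fs) + 1L]] <- mk_f(ZAZPy, kl)
  for (kl in sym_pairs) fs[[length(fs) + 1L]] <- mk_f(WWtPy, kl)
  for (kl in sym_pairs) fs[[length(fs) + 1L]] <- mk_f(Py, kl)

  Pf <- lapply(fs, function(f) {
    rf <- as.numeric(Matrix::crossprod(Wall, f %*% R0i))
    solf <- matrix(as.numeric(Matrix::solve(st$ch, rf)), ncol = nt)
    (f - as.matrix(Wall %*% solf)) %*% R0i
  })
  np <- length(fs)
  AI <- matrix(0, np, np)
  for (i in seq_len(np)) for (j in i:np) {
    AI[i, j] <- AI[j, i] <- 0.5 * sum(fs[[i]] * Pf[[j]])
  }
  V <- solve(AI + diag(1e-10, np))
  if (univariate || nt == 1) {
    g <- G0[1, 1]; p <- P0[1, 1]; r <- R0[1, 1]; vp <- g + p + r
    grad <- c((vp - g) / vp^2, -g / vp^2, -g / vp^2)
    return(list(h2 = rep(sqrt(max(0, grad %*% V %*% grad)), 2), rg = 0))
  }
  # parameter order: g11,g12,g22, p11,p12,p22, r11,r12,r22
  se_h2 <- numeric(2)
  for (t in 1:2) {
    g <- G0[t, t]; vp <- G0[t, t] + P0[t, t] + R0[t, t]
    grad <- numeric(9)
    gi <- if (t == 1) 1L else 3L; pi_ <- if (t == 1) 4L else 6L
    ri <- if (t == 1) 7L else 9L
    grad[gi] <- (vp - g) / vp^2
    grad[pi_] <- -g / vp^2
    grad[ri] <- -g / vp^2
    se_h2[t] <- sqrt(max(0, grad %*% V %*% grad))
  }
  g11 <- G0[1, 1]; g12 <- G0[1, 2]; g22 <- G0[2, 2]
  grad <- numeric(9)
  grad[1] <- -0.5 * g12 / (g11^1.5 * sqrt(g22))
  grad[2] <- 1 / sqrt(g11 * g22)
  grad[3] <- -0.5 * g12 / (sqrt(g11) * g22^1.5)
  se_rg <- sqrt(max(0, grad %*% V %*% grad))
  list(h2 = se_h2, rg = se_rg)
}
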