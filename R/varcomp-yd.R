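#' Compute per-cow yield deviations from a fitted repeatability model
#'
#' A yield deviation (YD) is a cow's test-day records adjusted for the
#' estimated non-genetic effects and averaged: for each record,
#' y - X beta-hat (estimated fixed effects) and, by default, minus the
#' cow's permanent-environment BLUP, so that the additive genetic signal
#' (plus mendelian noise) is retained in the average. Cows with fewer than
#' `min_records` usable records are dropped; the number dropped is recorded
#' in `attr(x, "n_dropped")`.
#'
#' @param records the same test-day table the model was fitted to.
#' @param fit a [fit_bivariate_reml()] result.
#' @param min_records minimum records per cow (default 3).
#' @param subtract_pe subtract the permanent-environment BLUP (default
#'   TRUE); set FALSE to adjust for fixed effects only.
#' @return data.frame of class `yield_deviation_table`: `cow`, `n_records`,
#'   and one YD column per trait.
#' @export
compute_yield_deviations <- function(records, fit, min_records = 3L,
                                     subtract_pe = TRUE) {
  stopifnot(inherits(fit, "varcomp_fit"))
  des <- fit$design
  rec <- records[des$records_used, , drop = FALSE]
  X <- des$X
  adj <- des$Y - as.matrix(X %*% fit$beta)
  if (subtract_pe) {
    pe <- fit$p[match(rec$cow, rownames(fit$p)), , drop = FALSE]
    adj <- adj - pe
  }
  cow_f <- factor(rec$cow, levels = des$cows)
  n_by <- as.integer(table(cow_f))
  yd <- apply(adj, 2, function(v) tapply(v, cow_f, mean))
  yd <- matrix(yd, ncol = ncol(adj))
  keep <- n_by >= min_records
  traits <- if (des$univariate) fit$traits[1] else fit$traits
  out <- data.frame(cow = des$cows[keep], n_records = n_by[keep],
                    stringsAsFactors = FALSE)
  for (k in seq_along(traits)) out[[traits[k]]] <- yd[keep, k]
  if (!all(is.finite(as.matrix(out[traits]))))
    stop("non-finite yield deviations produced")
  attr(out, "n_dropped") <- sum(!keep)
  class(out) <- c("yield_deviation_table", "data.frame")
  out
}
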