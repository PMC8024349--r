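#' Simulate a multi-generation cow pedigree
#'
#' Builds a trio pedigree (animal, sire, dam) with founder sires and founder
#' dams of unknown parentage and `n_generations` generations of females below
#' them. Each non-founder female draws a sire uniformly from the sire pool
#' and a dam uniformly (without replacement within a generation) from the
#' females of the previous generation, so half-sib families dominate and
#' inbreeding stays low. Phenotyped cows are the non-founder females.
#'
#' @param config a [sim_config()]; uses `n_cows`, `n_sires`,
#'   `n_generations`, `seed`.
#' @return a `data.frame` of class `pedigree_table` with columns
#'   `id`, `sire`, `dam` (character; `NA` for unknown), `sex`
#'   (`"M"`/`"F"`), `generation` (0 = founder) and `phenotyped` (logical).
#' @export
simulate_pedigree <- function(config) {
  config <- validate_sim_config(config)
  set.seed(sim_subseed(config$seed, 1L))
  n_gen <- max(2L, config$n_generations)
  n_cows <- config$n_cows
  n_sires <- config$n_sires
  # founder dams sized so each later generation can draw distinct dams
  per_gen <- ceiling(n_cows / n_gen)
  n_fdams <- per_gen
  sires <- sprintf("S%04d", seq_len(n_sires))
  fdams <- sprintf("D%04d", seq_len(n_fdams))
  ped <- data.frame(
    id = c(sires, fdams),
    sire = NA_character_, dam = NA_character_,
    sex = c(rep("M", n_sires), rep("F", n_fdams)),
    generation = 0L, phenotyped = FALSE,
    stringsAsFactors = FALSE)
  prev <- fdams
  made <- 0L
  for (g in seq_len(n_gen)) {
    n_this <- if (g == n_gen) n_cows - made else min(per_gen, n_cows - made)
    if (n_this <= 0L) break
    ids <- sprintf("C%05d", made + seq_len(n_this))
    dam_pool <- if (length(prev) >= n_this) sample(prev, n_this)
                else sample(prev, n_this, replace = TRUE)
    gen <- data.frame(
      id = ids,
      sire = sample(sires, n_this, replace = TRUE),
      dam = dam_pool,
      sex = "F", generation = g, phenotyped = TRUE,
      stringsAsFactors = FALSE)
    ped <- rbind(ped, gen)
    prev <- ids
    made <- made + n_this
  }
  class(ped) <- c("pedigree_table", "data.frame")
  ped
}

#' Topologically sort a pedigree, erroring on cycles
#'
#' Parents are placed before offspring; unknown parents (`NA`) are roots.
#' A cycle (an animal that is its own ancestor) is a hard error naming a
#' member of the cycle.
#'
#' @param ped data.frame with columns `id`, `sire`, `dam`.
#' @return the pedigree reordered parents-first.
#' @export
pedigree_sort <- function(ped) {
  ids <- ped$id
  idx <- seq_along(ids)
  names(idx) <- ids
  si <- idx[ped$sire]; di <- idx[ped$dam]   # NA for unknown/missing parents
  indeg <- as.integer(!is.na(si)) + as.integer(!is.na(di))
  children <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    if (!is.na(si[i])) children[[si[i]]] <- c(children[[si[i]]], i)
    if (!is.na(di[i])) children[[di[i]]] <- c(children[[di[i]]], i)
  }
  queue <- which(indeg == 0L)
  order <- integer(0)
  while (length(queue)) {
    i <- queue[1L]; queue <- queue[-1L]
    order <- c(order, i)
    for (ch in children[[i]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(order) < length(ids)) {
    bad <- ids[indeg > 0L]
    stop("pedigree contains a cycle involving: ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  ped[order, , drop = FALSE]
}
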