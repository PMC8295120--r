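#' Boltzmann weights of a set of free energies
#'
#' w_i = exp(-G_i/RT) / sum_j exp(-G_j/RT), computed with the usual
#' minimum-energy shift so that any finite input is safe from overflow.
#' Names on the input are preserved on the weights.
#'
#' @param free_energies Numeric vector of free energies, kcal/mol.
#' @param cond \code{\link{thermo_conditions}}.
#' @return Probability vector of the same length and order, summing to 1.
#' @examples
#' cond <- thermo_conditions()
#' boltzmann_weights(c(0, rt(cond) * log(2)), cond) # 2/3, 1/3
#' @export
boltzmann_weights <- function(free_energies, cond = thermo_conditions()) {
  .check_ensemble(free_energies)
  u <- exp(-(free_energies - min(free_energies)) / rt(cond))
  u / sum(u)
}

#' Ensemble free energy by log-sum-exp
#'
#' The free energy of a set of states: G_ens = -RT ln sum_i exp(-G_i/RT),
#' evaluated with a minimum-energy shift. It equals G for a single state and
#' G - RT ln(n) for n degenerate states, and is never above the minimum
#' state free energy.
#'
#' @inheritParams boltzmann_weights
#' @return Ensemble free energy, kcal/mol.
#' @export
ensemble_free_energy <- function(free_energies, cond = thermo_conditions()) {
  .check_ensemble(free_energies)
  gmin <- min(free_energies)
  gmin - rt(cond) * log(sum(exp(-(free_energies - gmin) / rt(cond))))
}

.check_ensemble <- function(free_energies) {
  if (length(free_energies) == 0L)
    stop("empty ensemble: at least one conformer free energy is required")
  .check_finite(free_energies, "free_energies")
}

#' Conformer free-energy table
#'
#' Validates a per-conformer free-energy component table: one row per
#' conformer with its gas-phase energy and, per solvent, a thermal
#' correction and a solvation free energy. The octanol columns may be
#' absent or NA for aqueous-only (pKa) data sets, but within a compound a
#' solvent must be either fully present or fully absent.
#'
#' @param x A data.frame with columns \code{compound_id},
#'   \code{conformer_id}, \code{gas_energy_kcal}, \code{thermal_water_kcal},
#'   \code{dgsolv_water_kcal} and optionally \code{thermal_octanol_kcal},
#'   \code{dgsolv_octanol_kcal} (all energies kcal/mol).
#' @return \code{x} with class \code{conformer_table} prepended.
#' @export
conformer_table <- function(x) {
  x <- as.data.frame(x)
  need <- c("compound_id", "conformer_id", "gas_energy_kcal",
            "thermal_water_kcal", "dgsolv_water_kcal")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("conformer table is missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(x) == 0L) stop("conformer table has no rows")
  key <- paste(x$compound_id, x$conformer_id, sep = "\r")
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1L]
    stop("duplicate (compound_id, conformer_id) row: ",
         gsub("\r", "/", d, fixed = TRUE))
  }
  for (col in c("thermal_octanol_kcal", "dgsolv_octanol_kcal"))
    if (is.null(x[[col]])) x[[col]] <- NA_real_
  class(x) <- unique(c("conformer_table", class(x)))
  x
}

#' Total per-conformer free energy in one solvent
#'
#' G_total = gas-phase energy + solvent thermal correction + solvation free
#' energy, the quantity entering the Boltzmann weighting in that solvent.
#'
#' @param conformers A \code{\link{conformer_table}} (or data.frame with its
#'   columns), typically the rows of one compound.
#' @param solvent \code{"water"} or \code{"octanol"}.
#' @return Numeric vector of total free energies, one per row, named by
#'   \code{conformer_id}.
#' @export
total_free_energy <- function(conformers, solvent = c("water", "octanol")) {
  solvent <- match.arg(solvent)
  conformers <- conformer_table(conformers)
  th <- conformers[[paste0("thermal_", solvent, "_kcal")]]
  ds <- conformers[[paste0("dgsolv_", solvent, "_kcal")]]
  g <- conformers$gas_energy_kcal + th + ds
  bad <- !is.finite(g)
  if (any(bad))
    stop(sprintf("missing %s free-energy component for compound %s, conformer %s",
                 solvent, conformers$compound_id[bad][1L],
                 conformers$conformer_id[bad][1L]))
  names(g) <- conformers$conformer_id
  g
}

#' Compound log P from a water/octanol conformer ensemble
#'
#' Computes the ensemble free energy of the compound separately in water
#' and in n-octanol and converts their difference to
#' log P = (G_ens(water) - G_ens(octanol)) / (RT ln10).
#'
#' With \code{aggregation = "free_energy"} (the default) each phase is
#' aggregated with the partition-function rule
#' (\code{\link{ensemble_free_energy}}); \code{"weighted_mean"} instead uses
#' the Boltzmann-weighted arithmetic mean of the conformer free energies in
#' each phase, which drops the conformational entropy term and is provided
#' for sensitivity analysis.
#'
#' @param conformers \code{\link{conformer_table}} rows of a single compound,
#'   with both solvents present.
#' @param cond \code{\link{thermo_conditions}}.
#' @param aggregation \code{"free_energy"} or \code{"weighted_mean"}.
#' @return An object of class \code{logp_result}: a list with
#'   \code{compound_id}, \code{logp}, and per-phase \code{water} /
#'   \code{octanol} elements each carrying \code{weights} (named Boltzmann
#'   populations) and \code{ensemble_free_energy}.
#' @export
compound_logp <- function(conformers, cond = thermo_conditions(),
                          aggregation = c("free_energy", "weighted_mean")) {
  aggregation <- match.arg(aggregation)
  conformers <- conformer_table(conformers)
  cid <- unique(conformers$compound_id)
  if (length(cid) != 1L)
    stop("compound_logp expects the conformers of a single compound, got: ",
         paste(cid, collapse = ", "))
  phase <- lapply(c(water = "water", octanol = "octanol"), function(s) {
    g <- total_free_energy(conformers, s)
    w <- boltzmann_weights(g, cond)
    ge <- switch(aggregation,
                 free_energy   = ensemble_free_energy(g, cond),
                 weighted_mean = sum(w * g))
    list(weights = w, ensemble_free_energy = ge)
  })
  lp <- (phase$water$ensemble_free_energy - phase$octanol$ensemble_free_energy) /
    rt_ln10(cond)
  structure(list(compound_id = cid, logp = lp,
                 water = phase$water, octanol = phase$octanol,
                 aggregation = aggregation),
            class = "logp_result")
}

#' @export
print.logp_result <- function(x, ...) {
  cat(sprintf("%s: log P = %.4f  (G_ens water %.4f, octanol %.4f kcal/mol, %d conformers, %s)\n",
              x$compound_id, x$logp, x$water$ensemble_free_energy,
              x$octanol$ensemble_free_energy, length(x$water$weights),
              x$aggregation))
  invisible(x)
}

#' log P for every compound in a conformer table
#'
#' @param conformers A \code{\link{conformer_table}} covering one or more
#'   compounds.
#' @inheritParams compound_logp
#' @return data.frame with columns \code{compound_id}, \code{logp}, ordered
#'   by compound_id; the per-compound \code{logp_result} objects are
#'   attached as attribute \code{"results"}.
#' @export
logp_table <- function(conformers, cond = thermo_conditions(),
                       aggregation = c("free_energy", "weighted_mean")) {
  aggregation <- match.arg(aggregation)
  conformers <- conformer_table(conformers)
  chunks <- split(as.data.frame(conformers), conformers$compound_id)
  ids <- sort(names(chunks))
  res <- lapply(chunks[ids], function(ch)
    compound_logp(conformer_table(ch), cond, aggregation))
  out <- data.frame(compound_id = ids,
                    logp = vapply(res, `[[`, numeric(1), "logp"),
                    stringsAsFactors = FALSE)
  attr(out, "results") <- stats::setNames(res, ids)
  out
}

#' Remove energetically redundant conformers
#'
#' Collapses groups of conformers whose total free energies in the chosen
#' solvent are pairwise within \code{energy_tol}, keeping one representative
#' per group (the lowest-energy member, ties broken by lexicographically
#' smallest conformer_id). The global minimum-energy conformer is always
#' retained. \code{energy_tol = 0} disables pruning. An automated stand-in
#' for manual inspection of near-duplicate conformations; with the default
#' tight tolerance it removes only numerical duplicates.
#'
#' @param conformers \code{\link{conformer_table}} rows of a single compound.
#' @param solvent Solvent whose total free energies define redundancy.
#' @param energy_tol Non-negative window in kcal/mol.
#' @return The pruned \code{conformer_table}, original row order preserved.
#' @export
prune_redundant <- function(conformers, solvent = c("water", "octanol"),
                            energy_tol = 1e-6) {
  solvent <- match.arg(solvent)
  if (!is.numeric(energy_tol) || length(energy_tol) != 1L ||
      !is.finite(energy_tol) || energy_tol < 0)
    stop("'energy_tol' must be a single non-negative number (kcal/mol)")
  conformers <- conformer_table(conformers)
  if (energy_tol == 0) return(conformers)
  g <- total_free_energy(conformers, solvent)
  ord <- order(g, conformers$conformer_id, method = "radix")
  keep_id <- character(0)
  grp_g <- numeric(0); grp_rep <- NA_integer_
  flush <- function() if (!is.na(grp_rep)) keep_id <<- c(keep_id, conformers$conformer_id[grp_rep])
  for (i in ord) {
    if (length(grp_g) && all(abs(g[i] - grp_g) <= energy_tol)) {
      grp_g <- c(grp_g, g[i]) # joins: representative stays the lowest/first
    } else {
      flush()
      grp_g <- g[i]; grp_rep <- i
    }
  }
  flush()
  conformers[conformers$conformer_id %in% keep_id, , drop = FALSE]
}
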