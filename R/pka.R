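#' Protonation microstate
#'
#' One protonation/tautomeric form of a compound at a defined formal charge,
#' carrying the aqueous free energies of its conformers (kcal/mol). The
#' conformer spread is collapsed with \code{\link{microstate_free_energy}}
#' before any pKa arithmetic.
#'
#' @param microstate_id Identifier, e.g. \code{"SM99_micro001"}.
#' @param compound_id Parent compound identifier.
#' @param formal_charge Integer formal charge of the microstate.
#' @param conformer_free_energies Numeric vector (>= 1) of aqueous conformer
#'   free energies, kcal/mol.
#' @return Object of class \code{microstate}.
#' @export
microstate <- function(microstate_id, compound_id, formal_charge,
                       conformer_free_energies) {
  if (!is.character(microstate_id) || length(microstate_id) != 1L || !nzchar(microstate_id))
    stop("'microstate_id' must be a non-empty string")
  if (length(formal_charge) != 1L || formal_charge != round(formal_charge))
    stop("'formal_charge' must be a single integer")
  .check_ensemble(conformer_free_energies)
  structure(list(microstate_id = microstate_id,
                 compound_id = compound_id,
                 formal_charge = as.integer(formal_charge),
                 conformer_free_energies = as.numeric(conformer_free_energies)),
            class = "microstate")
}

#' Set of microstates of one compound
#'
#' @param compound_id Compound identifier.
#' @param microstates List of \code{\link{microstate}} objects with unique
#'   ids, all belonging to \code{compound_id}.
#' @param dialect How the free energies are to be read:
#'   \code{"absolute_aqueous"} (absolute aqueous free energies; the
#'   deprotonation cycle adds the proton term) or
#'   \code{"relative_transition"} (deprotonation free energies relative to a
#'   reference microstate with the proton/gas terms already folded in; the
#'   proton term is bypassed downstream).
#' @param reference Reference microstate id, required for the relative
#'   dialect.
#' @return Object of class \code{microstate_set}.
#' @export
microstate_set <- function(compound_id, microstates,
                           dialect = c("absolute_aqueous", "relative_transition"),
                           reference = NULL) {
  dialect <- match.arg(dialect)
  if (!length(microstates)) stop("'microstates' must be a non-empty list")
  if (!all(vapply(microstates, inherits, logical(1), "microstate")))
    stop("'microstates' must all be microstate objects")
  ids <- vapply(microstates, `[[`, character(1), "microstate_id")
  if (anyDuplicated(ids))
    stop("duplicate microstate_id within compound ", compound_id, ": ",
         ids[duplicated(ids)][1L])
  owners <- vapply(microstates, `[[`, character(1), "compound_id")
  if (!all(owners == compound_id))
    stop("all microstates must belong to compound ", compound_id)
  if (dialect == "relative_transition" &&
      (is.null(reference) || !reference %in% ids))
    stop("relative_transition dialect requires 'reference' naming one microstate")
  structure(list(compound_id = compound_id,
                 microstates = stats::setNames(microstates, ids),
                 dialect = dialect, reference = reference),
            class = "microstate_set")
}

#' Microstate free energy over its conformers
#'
#' Boltzmann (log-sum-exp) collapse of the microstate's conformer aqueous
#' free energies into a single microstate free energy.
#'
#' @param m A \code{\link{microstate}}.
#' @param cond \code{\link{thermo_conditions}}.
#' @return Free energy, kcal/mol.
#' @export
microstate_free_energy <- function(m, cond = thermo_conditions()) {
  stopifnot(inherits(m, "microstate"))
  ensemble_free_energy(m$conformer_free_energies, cond)
}

#' Microscopic pKa of an acid/base microstate pair
#'
#' Applies the deprotonation cycle to the ensemble free energies of one
#' protonated and one deprotonated microstate. The base must carry exactly
#' one fewer proton (formal charge one lower) than the acid.
#'
#' @param acid,base \code{\link{microstate}} objects with
#'   \code{base$formal_charge == acid$formal_charge - 1}.
#' @param proton \code{\link{proton_parameters}}, or \code{NULL} when the
#'   free energies are relative-transition values with the proton term
#'   already folded in.
#' @param cond \code{\link{thermo_conditions}}.
#' @return Microscopic pKa.
#' @export
micro_pka <- function(acid, base, proton = proton_parameters(),
                      cond = thermo_conditions()) {
  stopifnot(inherits(acid, "microstate"), inherits(base, "microstate"))
  if (base$formal_charge != acid$formal_charge - 1L)
    stop(sprintf("charge mismatch: base %s has charge %d, expected %d (acid %s charge %d minus 1)",
                 base$microstate_id, base$formal_charge,
                 acid$formal_charge - 1L, acid$microstate_id, acid$formal_charge))
  pka_from_deprotonation(microstate_free_energy(acid, cond),
                         microstate_free_energy(base, cond),
                         proton = .proton_or_null(proton), cond = cond)
}

# relative-transition dialect folds the proton term into the free energies
.proton_or_null <- function(proton) {
  if (is.null(proton)) proton_parameters(0, 0, 0) else proton
}

#' Macroscopic pKa of a compound from its microstates
#'
#' The free energy of each total-charge macrostate is the log-sum-exp over
#' all conformers of all its tautomeric microstates (flat pooling over the
#' charge state's partition function, identical to collapsing each
#' microstate first and pooling the microstate free energies). The
#' macroscopic pKa between charge q (acid) and q-1 (base) is then
#' (G_macro(q-1) + G(H+) - G_macro(q)) / (RT ln10). All microscopic
#' acid/base pair pKas are reported alongside.
#'
#' @param ms A \code{\link{microstate_set}} containing at least one
#'   microstate at \code{acid_charge} and one at \code{acid_charge - 1}.
#' @param acid_charge Formal charge of the protonated macrostate.
#' @param proton \code{\link{proton_parameters}}; ignored (treated as zero)
#'   when the set's dialect is \code{relative_transition}.
#' @param cond \code{\link{thermo_conditions}}.
#' @return Object of class \code{pka_result}: list with \code{compound_id},
#'   \code{macro_pka}, \code{micro_pkas} (data.frame acid_id, base_id, pka)
#'   and \code{charge_state_free_energies} (named by charge, kcal/mol).
#' @export
macro_pka <- function(ms, acid_charge = 0L, proton = proton_parameters(),
                      cond = thermo_conditions()) {
  stopifnot(inherits(ms, "microstate_set"))
  if (ms$dialect == "relative_transition") proton <- NULL
  charges <- vapply(ms$microstates, `[[`, integer(1), "formal_charge")
  for (q in c(acid_charge, acid_charge - 1L))
    if (!any(charges == q))
      stop(sprintf("compound %s has no microstate at formal charge %d",
                   ms$compound_id, q))
  g_macro <- function(q) {
    pool <- unlist(lapply(ms$microstates[charges == q],
                          `[[`, "conformer_free_energies"), use.names = FALSE)
    ensemble_free_energy(pool, cond)
  }
  gq  <- g_macro(acid_charge)
  gq1 <- g_macro(acid_charge - 1L)
  macro <- pka_from_deprotonation(gq, gq1, proton = .proton_or_null(proton),
                                  cond = cond)
  acids <- ms$microstates[charges == acid_charge]
  bases <- ms$microstates[charges == acid_charge - 1L]
  grid <- expand.grid(acid_id = names(acids), base_id = names(bases),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$pka <- mapply(function(a, b) micro_pka(acids[[a]], bases[[b]], proton, cond),
                     grid$acid_id, grid$base_id)
  structure(list(compound_id = ms$compound_id, macro_pka = macro,
                 micro_pkas = grid,
                 charge_state_free_energies =
                   stats::setNames(c(gq, gq1),
                                   as.character(c(acid_charge, acid_charge - 1L)))),
            class = "pka_result")
}

#' @export
print.pka_result <- function(x, ...) {
  cat(sprintf("%s: macroscopic pKa = %.4f over %d microscopic equilibria\n",
              x$compound_id, x$macro_pka, nrow(x$micro_pkas)))
  invisible(x)
}

#' Check a microstate table against a reported macroscopic pKa
#'
#' Recomputes the macroscopic pKa from the microstate free energies and
#' flags a discrepancy larger than \code{tol}. This catches bookkeeping
#' errors in submitted microstate files, such as two tautomers' free-energy
#' values having been swapped, which silently shift the recomputed
#' macroscopic value away from the intended one.
#'
#' @inheritParams macro_pka
#' @param reported_macro_pka The macroscopic pKa claimed for this table.
#' @param tol Discrepancy tolerance in pKa units; default 0.10.
#' @return Object of class \code{pka_validation}: list with
#'   \code{compound_id}, \code{reported}, \code{recomputed},
#'   \code{discrepancy}, logical \code{flagged}, and
#'   \code{microstate_free_energies} (named, kcal/mol).
#' @export
validate_microstate_table <- function(ms, reported_macro_pka, tol = 0.10,
                                      acid_charge = 0L,
                                      proton = proton_parameters(),
                                      cond = thermo_conditions()) {
  stopifnot(inherits(ms, "microstate_set"))
  if (!is.numeric(tol) || length(tol) != 1L || !is.finite(tol) || tol <= 0)
    stop("'tol' must be a single positive number (pKa units)")
  res <- macro_pka(ms, acid_charge, proton, cond)
  disc <- res$macro_pka - reported_macro_pka
  structure(list(compound_id = ms$compound_id,
                 reported = reported_macro_pka,
                 recomputed = res$macro_pka,
                 discrepancy = disc,
                 flagged = abs(disc) > tol,
                 tol = tol,
                 microstate_free_energies =
                   vapply(ms$microstates, microstate_free_energy,
                          numeric(1), cond = cond)),
            class = "pka_validation")
}

#' @export
print.pka_validation <- function(x, ...) {
  cat(sprintf("%s: reported pKa %.4f, recomputed %.4f (discrepancy %+.4f, tol %.2f) -> %s\n",
              x$compound_id, x$reported, x$recomputed, x$discrepancy, x$tol,
              if (x$flagged) "FLAGGED" else "consistent"))
  invisible(x)
}

#' Build microstate sets from a long-format microstate table
#'
#' @param x data.frame with columns \code{compound_id},
#'   \code{microstate_id}, \code{formal_charge}, \code{conformer_id},
#'   \code{free_energy_kcal} (one row per conformer), as produced by
#'   \code{\link{read_microstate_table}} or
#'   \code{\link{generate_synthetic}}; its \code{dialect} attribute (and
#'   \code{reference}, if relative) is honoured.
#' @return Named list of \code{\link{microstate_set}} objects, one per
#'   compound, ordered by compound_id.
#' @export
as_microstate_sets <- function(x) {
  x <- as.data.frame(x)
  need <- c("compound_id", "microstate_id", "formal_charge",
            "conformer_id", "free_energy_kcal")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("microstate table is missing column(s): ", paste(miss, collapse = ", "))
  dialect <- attr(x, "dialect")
  if (is.null(dialect)) dialect <- "absolute_aqueous"
  reference <- attr(x, "reference")
  chunks <- split(x, x$compound_id)
  ids <- sort(names(chunks))
  out <- lapply(ids, function(cid) {
    sub <- chunks[[cid]]
    ms <- lapply(split(sub, sub$microstate_id), function(rows) {
      q <- unique(rows$formal_charge)
      if (length(q) != 1L)
        stop("inconsistent formal_charge for microstate ",
             rows$microstate_id[1L])
      microstate(rows$microstate_id[1L], cid, q, rows$free_energy_kcal)
    })
    microstate_set(cid, unname(ms), dialect = dialect,
                   reference = if (identical(dialect, "relative_transition"))
                     reference else NULL)
  })
  stats::setNames(out, ids)
}

#' Macroscopic pKa for every compound in a microstate table
#'
#' @inheritParams as_microstate_sets
#' @inheritParams macro_pka
#' @return data.frame with columns \code{compound_id}, \code{pka}, ordered
#'   by compound_id; per-compound \code{pka_result} objects attached as
#'   attribute \code{"results"}.
#' @export
pka_table <- function(x, acid_charge = 0L, proton = proton_parameters(),
                      cond = thermo_conditions()) {
  sets <- as_microstate_sets(x)
  res <- lapply(sets, macro_pka, acid_charge = acid_charge,
                proton = proton, cond = cond)
  out <- data.frame(compound_id = names(sets),
                    pka = vapply(res, `[[`, numeric(1), "macro_pka"),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "results") <- res
  out
}
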