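#' Specification for a synthetic free-energy data set
#'
#' Describes a set of invented compounds with known ground-truth log P and
#' macroscopic pKa, from which conformer- and microstate-level free-energy
#' tables are generated (\code{\link{generate_synthetic}}). Targets are
#' embedded exactly by construction: one free-energy block per compound is
#' back-solved so the Boltzmann aggregate reproduces the target, then
#' optional Gaussian noise of sd \code{energy_noise_sd} is added to every
#' emitted component.
#'
#' @param n_compounds Number of compounds.
#' @param conformer_range Integer range (length 2) of conformers per
#'   compound/microstate, within [1, 20].
#' @param logp_range Range the true log P values are drawn from (log units).
#' @param pka_range Range the true macroscopic pKa values are drawn from.
#' @param tautomer_range Integer range of tautomeric microstates per charge
#'   state.
#' @param energy_noise_sd Standard deviation (kcal/mol) of Gaussian noise
#'   added to every free-energy component; 0 gives exact recovery.
#' @param seed Integer RNG seed; generation is deterministic given the spec.
#' @return Object of class \code{synthetic_spec}.
#' @export
synthetic_spec <- function(n_compounds = 50L,
                           conformer_range = c(1L, 20L),
                           logp_range = c(-0.5, 4.5),
                           pka_range = c(4, 12),
                           tautomer_range = c(1L, 3L),
                           energy_noise_sd = 0,
                           seed = 1L) {
  chk_range <- function(r, what, lo = -Inf, hi = Inf, int = FALSE) {
    if (length(r) != 2L || !all(is.finite(r)) || r[1L] > r[2L])
      stop("'", what, "' must be a non-empty range c(lo, hi)")
    if (r[1L] < lo || r[2L] > hi)
      stop("'", what, "' must lie within [", lo, ", ", hi, "]")
    if (int && any(r != round(r))) stop("'", what, "' must be integer-valued")
    r
  }
  if (!is.numeric(n_compounds) || length(n_compounds) != 1L || n_compounds < 1)
    stop("'n_compounds' must be a positive integer")
  if (!is.numeric(energy_noise_sd) || length(energy_noise_sd) != 1L ||
      !is.finite(energy_noise_sd) || energy_noise_sd < 0)
    stop("'energy_noise_sd' must be a single non-negative number (kcal/mol)")
  structure(list(n_compounds = as.integer(n_compounds),
                 conformer_range = as.integer(chk_range(conformer_range,
                   "conformer_range", 1, 20, int = TRUE)),
                 logp_range = chk_range(logp_range, "logp_range"),
                 pka_range = chk_range(pka_range, "pka_range"),
                 tautomer_range = as.integer(chk_range(tautomer_range,
                   "tautomer_range", 1, Inf, int = TRUE)),
                 energy_noise_sd = energy_noise_sd,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

.sample_range <- function(r) if (r[1L] == r[2L]) r[1L] else sample(r[1L]:r[2L], 1L)

#' Generate a synthetic conformer/microstate free-energy data set
#'
#' For each compound, conformer free-energy components (gas-phase energy,
#' per-solvent thermal correction and solvation free energy) and aqueous
#' microstate conformer free energies are drawn at chemically plausible
#' magnitudes; the octanol solvation energies are then shifted by a single
#' constant so the two-phase ensemble free energies reproduce the target
#' log P exactly, and the deprotonated-state energies likewise so the
#' charge-state partition functions reproduce the target macroscopic pKa
#' exactly (shift invariance of log-sum-exp makes both embeddings exact).
#' Gaussian noise, if requested, is added to every component afterwards.
#'
#' @param spec A \code{\link{synthetic_spec}}.
#' @param proton \code{\link{proton_parameters}} used in the embedded
#'   deprotonation cycle.
#' @param cond \code{\link{thermo_conditions}}.
#' @return List with \code{conformers} (a \code{\link{conformer_table}}),
#'   \code{microstates} (long microstate table, dialect
#'   \code{absolute_aqueous}), \code{reference} (compound_id, property,
#'   value rows carrying the ground truth as pseudo-experimental values),
#'   \code{truth} (data.frame compound_id, true_logp, true_pka, with the
#'   noise-free per-microstate free energies as attribute
#'   \code{"microstate_free_energies"}), and the \code{spec}.
#' @export
generate_synthetic <- function(spec, proton = proton_parameters(),
                               cond = thermo_conditions()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  wid <- max(3L, nchar(as.character(spec$n_compounds)))
  ids <- sprintf(paste0("SYN%0", wid, "d"), seq_len(spec$n_compounds))
  true_logp <- stats::runif(spec$n_compounds, spec$logp_range[1L], spec$logp_range[2L])
  true_pka  <- stats::runif(spec$n_compounds, spec$pka_range[1L], spec$pka_range[2L])

  conf_rows <- vector("list", spec$n_compounds)
  micro_rows <- vector("list", spec$n_compounds)
  truth_micro <- vector("list", spec$n_compounds)

  for (i in seq_len(spec$n_compounds)) {
    cid <- ids[i]
    # --- conformer table with exact embedded log P -------------------------
    nc <- .sample_range(spec$conformer_range)
    gas <- stats::runif(nc, -50, 0)
    th_w <- stats::runif(nc, 0, 5)
    th_o <- stats::runif(nc, 0, 5)
    ds_w <- stats::runif(nc, -15, 0)
    ds_o <- stats::runif(nc, -15, 0)
    g_w <- ensemble_free_energy(gas + th_w + ds_w, cond)
    g_o_target <- g_w - rt_ln10(cond) * true_logp[i]
    ds_o <- ds_o + (g_o_target - ensemble_free_energy(gas + th_o + ds_o, cond))
    conf_rows[[i]] <- data.frame(
      compound_id = cid,
      conformer_id = sprintf("conf%03d", seq_len(nc)),
      gas_energy_kcal = gas,
      thermal_water_kcal = th_w, thermal_octanol_kcal = th_o,
      dgsolv_water_kcal = ds_w, dgsolv_octanol_kcal = ds_o,
      stringsAsFactors = FALSE)

    # --- microstate table with exact embedded macroscopic pKa --------------
    g0 <- stats::runif(1, -50, 0) # compound-level aqueous baseline
    draw_charge <- function(charge, label) {
      nt <- .sample_range(spec$tautomer_range)
      do.call(rbind, lapply(seq_len(nt), function(j) {
        nk <- .sample_range(spec$conformer_range)
        off <- stats::runif(1, 0, 3)              # tautomer gap
        g <- g0 + off + stats::runif(nk, 0, 2)    # conformer spread
        data.frame(compound_id = cid,
                   microstate_id = sprintf("%s_%s%03d", cid, label, j),
                   formal_charge = charge,
                   conformer_id = sprintf("conf%03d", seq_len(nk)),
                   free_energy_kcal = g, stringsAsFactors = FALSE)
      }))
    }
    acid <- draw_charge(0L, "acid")
    base <- draw_charge(-1L, "base")
    g_acid <- ensemble_free_energy(acid$free_energy_kcal, cond)
    # macro pKa = (G(-1) + G(H+) - G(0)) / RTln10  =>  solve for G(-1)
    g_base_target <- true_pka[i] * rt_ln10(cond) + g_acid - proton_total(proton)
    base$free_energy_kcal <- base$free_energy_kcal +
      (g_base_target - ensemble_free_energy(base$free_energy_kcal, cond))
    micro_rows[[i]] <- rbind(acid, base)
    mi <- rbind(acid, base)
    truth_micro[[i]] <- data.frame(
      compound_id = cid,
      microstate_id = unique(mi$microstate_id),
      free_energy_kcal = vapply(split(mi$free_energy_kcal, mi$microstate_id)[unique(mi$microstate_id)],
                                ensemble_free_energy, numeric(1), cond = cond),
      stringsAsFactors = FALSE, row.names = NULL)
  }

  conf <- do.call(rbind, conf_rows)
  micro <- do.call(rbind, micro_rows)
  if (spec$energy_noise_sd > 0) {
    for (col in c("gas_energy_kcal", "thermal_water_kcal", "thermal_octanol_kcal",
                  "dgsolv_water_kcal", "dgsolv_octanol_kcal"))
      conf[[col]] <- conf[[col]] + stats::rnorm(nrow(conf), 0, spec$energy_noise_sd)
    micro$free_energy_kcal <- micro$free_energy_kcal +
      stats::rnorm(nrow(micro), 0, spec$energy_noise_sd)
  }
  rownames(conf) <- rownames(micro) <- NULL
  attr(micro, "dialect") <- "absolute_aqueous"

  reference <- rbind(
    data.frame(compound_id = ids, property = "logp", value = true_logp,
               stringsAsFactors = FALSE),
    data.frame(compound_id = ids, property = "pka", value = true_pka,
               stringsAsFactors = FALSE))
  reference <- reference[order(reference$compound_id, reference$property), ]
  rownames(reference) <- NULL
  truth <- data.frame(compound_id = ids, true_logp = true_logp,
                      true_pka = true_pka, stringsAsFactors = FALSE)
  attr(truth, "microstate_free_energies") <- do.call(rbind, truth_micro)
  list(conformers = conformer_table(conf), microstates = micro,
       reference = reference, truth = truth, spec = spec)
}

#' Swap two microstates' free energies (error-scenario generator)
#'
#' Exchanges the conformer free-energy values of two same-charge
#' microstates in a long microstate table, reproducing the bookkeeping
#' error class in which two tautomers' rows are flipped in a submitted
#' file. Applying the same swap twice restores the original table. Used to
#' exercise \code{\link{validate_microstate_table}}.
#'
#' @param x Long microstate table (see \code{\link{as_microstate_sets}}).
#' @param swap_pair Length-2 character vector of microstate ids to swap;
#'   both must exist and share a formal charge.
#' @return The table with the two microstates' free-energy sets exchanged,
#'   re-sorted by (compound_id, microstate_id, conformer_id).
#' @export
corrupt_microstates <- function(x, swap_pair) {
  stopifnot(length(swap_pair) == 2L)
  x <- as.data.frame(x)
  dialect <- attr(x, "dialect"); reference <- attr(x, "reference")
  for (id in swap_pair)
    if (!id %in% x$microstate_id) stop("unknown microstate_id: ", id)
  q <- vapply(swap_pair, function(id)
    unique(x$formal_charge[x$microstate_id == id]), numeric(1))
  if (q[1L] != q[2L])
    stop(sprintf("cannot swap microstates of different formal charge (%s: %d, %s: %d)",
                 swap_pair[1L], as.integer(q[1L]), swap_pair[2L], as.integer(q[2L])))
  a <- x$microstate_id == swap_pair[1L]
  b <- x$microstate_id == swap_pair[2L]
  x$microstate_id[a] <- swap_pair[2L]
  x$microstate_id[b] <- swap_pair[1L]
  x <- x[order(x$compound_id, x$microstate_id, x$conformer_id, method = "radix"), ]
  rownames(x) <- NULL
  attr(x, "dialect") <- dialect; attr(x, "reference") <- reference
  x
}
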