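# Gas constant per supported energy unit, in <unit> / (mol K) (hartree: per K).
GAS_CONSTANT <- c(kcal_mol = 1.987204259e-3,
                  kj_mol   = 8.31446261815324e-3,
                  hartree  = 3.166811563e-6)

#' Drop high-energy conformers outside an energy window
#'
#' Retains only conformers whose relative energy lies within `window` of the
#' most stable one, the usual pre-filter before Boltzmann averaging (a 3.0
#' kcal/mol = 12.5 kJ/mol window is the common choice for shielding
#' ensembles). The minimum-energy conformer always survives.
#'
#' @param ensemble A `conformer_tbl` (see [read_conformer_table()]).
#' @param window Positive energy cutoff, in the same unit as the ensemble's
#'   `rel_energy` column.
#' @return The filtered ensemble, energies re-zeroed (a no-op here since the
#'   minimum survives).
#' @export
energy_window_filter <- function(ensemble, window = 3.0) {
  validate_ensemble(ensemble)
  if (!is.numeric(window) || length(window) != 1L || window <= 0) {
    abort("`window` must be a single positive energy value")
  }
  rel <- ensemble$rel_energy - min(ensemble$rel_energy)
  out <- ensemble[rel <= window, , drop = FALSE]
  out$rel_energy <- out$rel_energy - min(out$rel_energy)
  out
}

#' Boltzmann population weights from relative conformer energies
#'
#' Computes \eqn{w_i = \exp(-\Delta E_i / RT) / \sum_j \exp(-\Delta E_j / RT)}.
#' Weights depend only on energy differences, so adding a constant to every
#' energy leaves them unchanged.
#'
#' @inheritParams energy_window_filter
#' @param temperature Absolute temperature in kelvin (default 298.15 K).
#' @param energy_unit Unit of `rel_energy`: `"kcal_mol"`, `"kj_mol"` or
#'   `"hartree"`.
#' @return Tibble with columns `conformer_id`, `weight`; weights sum to 1.
#' @examples
#' ens <- generate_conformer_ensemble(n_conformers = 4, n_atoms = 3, seed = 7)
#' boltzmann_weights(ens)
#' @export
boltzmann_weights <- function(ensemble, temperature = 298.15,
                              energy_unit = c("kcal_mol", "kj_mol", "hartree")) {
  validate_ensemble(ensemble)
  energy_unit <- arg_match(energy_unit)
  if (!is.numeric(temperature) || length(temperature) != 1L || temperature <= 0) {
    abort("`temperature` must be a single positive value in kelvin")
  }
  rt <- GAS_CONSTANT[[energy_unit]] * temperature
  e <- ensemble$rel_energy - min(ensemble$rel_energy)  # guards the exponentials
  w <- exp(-e / rt)
  tibble(conformer_id = ensemble$conformer_id, weight = w / sum(w))
}

#' Boltzmann-averaged isotropic shieldings
#'
#' Population-weighted mean shielding per atom over the ensemble.
#'
#' @inheritParams energy_window_filter
#' @param weights Tibble `conformer_id`, `weight` as returned by
#'   [boltzmann_weights()]; must cover exactly the ensemble's conformers.
#' @return Tibble with columns `label`, `shielding` (ppm), atoms in ensemble
#'   column order.
#' @export
average_shieldings <- function(ensemble, weights) {
  validate_ensemble(ensemble)
  if (!setequal(weights$conformer_id, ensemble$conformer_id) ||
      nrow(weights) != nrow(ensemble)) {
    abort("`weights` must cover exactly the ensemble's conformer ids")
  }
  w <- weights$weight[match(ensemble$conformer_id, weights$conformer_id)]
  labs <- ensemble_labels(ensemble)
  sh <- as.matrix(ensemble[, labs, drop = FALSE])
  tibble(label = labs, shielding = as.numeric(crossprod(sh, w)))
}

#' Reference-standard shieldings for multistandard calibration
#'
#' Holds the calculated isotropic shieldings of the two reference compounds
#' at the level of theory used for the solute, plus their experimental
#' shifts. TMS defines 0 ppm by convention; benzene's experimental
#' \eqn{^{13}}C shift is 128.37 ppm.
#'
#' @param tms_sigma Calculated isotropic shielding of the TMS carbons (ppm).
#' @param benzene_sigma Calculated isotropic shielding of the benzene
#'   carbons (ppm).
#' @param benzene_delta_exp Experimental benzene shift (ppm).
#' @param tms_delta_exp Experimental TMS shift; 0 by definition.
#' @return A `calibration_standards` list.
#' @export
calibration_standards <- function(tms_sigma, benzene_sigma,
                                  benzene_delta_exp = 128.37,
                                  tms_delta_exp = 0) {
  vals <- c(tms_sigma = tms_sigma, benzene_sigma = benzene_sigma,
            benzene_delta_exp = benzene_delta_exp, tms_delta_exp = tms_delta_exp)
  if (any(!is.finite(vals))) abort("all calibration standards must be finite")
  if (tms_delta_exp != 0) abort("`tms_delta_exp` is 0 ppm by definition")
  structure(as.list(vals), class = "calibration_standards")
}

#' Multistandard calibration of shieldings into chemical shifts
#'
#' Converts Boltzmann-averaged isotropic shieldings to chemical shifts using
#' a chemically matched reference per carbon type: TMS for sp3 carbons
#' (\eqn{\delta = \sigma_{TMS} - \sigma}), benzene for sp2 carbons
#' (\eqn{\delta = \sigma_{benzene} - \sigma + \delta^{exp}_{benzene}}).
#' Carbonyl carbons are excluded from the benzene rule; which standard they
#' follow is set by `carbonyl_policy` (TMS by default).
#'
#' @param shieldings Tibble `label`, `shielding` (see [average_shieldings()]).
#' @param atom_index Tibble `label`, `hybridization` covering every shielded
#'   atom.
#' @param standards A [calibration_standards()] object.
#' @param carbonyl_policy Reference for carbonyl carbons: `"tms"` or
#'   `"benzene"`.
#' @param set_id Name for the resulting shift set column.
#' @param origin Origin tag of the resulting `shift_tbl`.
#' @return A one-set `shift_tbl` of calibrated shifts.
#' @export
calibrate_multistandard <- function(shieldings, atom_index, standards,
                                    carbonyl_policy = c("tms", "benzene"),
                                    set_id = "calc", origin = "calculated") {
  carbonyl_policy <- arg_match(carbonyl_policy)
  if (!inherits(standards, "calibration_standards")) {
    abort("`standards` must come from calibration_standards()")
  }
  missing <- setdiff(shieldings$label, atom_index$label)
  if (length(missing) > 0L) {
    abort(sprintf("atom label(s) absent from atom_index: %s",
                  paste(missing, collapse = ", ")))
  }
  hyb <- atom_index$hybridization[match(shieldings$label, atom_index$label)]
  check_hybridization(hyb)
  use_benzene <- hyb == "sp2" | (hyb == "carbonyl" & carbonyl_policy == "benzene")
  ref_sigma <- ifelse(use_benzene, standards$benzene_sigma, standards$tms_sigma)
  ref_delta <- ifelse(use_benzene, standards$benzene_delta_exp, standards$tms_delta_exp)
  delta <- ref_sigma - shieldings$shielding + ref_delta
  out <- tibble(label = shieldings$label, hybridization = hyb)
  out[[set_id]] <- delta
  new_shift_tbl(out, origin = origin)
}

#' Full shielding-to-shift pipeline for one conformer ensemble
#'
#' Convenience chain: energy-window filter, Boltzmann weights, weighted
#' shielding average, multistandard calibration. Weighting commutes with
#' calibration (calibration is affine), so averaging shieldings first is
#' equivalent to calibrating each conformer and averaging shifts.
#'
#' @inheritParams energy_window_filter
#' @inheritParams boltzmann_weights
#' @inheritParams calibrate_multistandard
#' @param energy_window Cutoff passed to [energy_window_filter()]; `NULL`
#'   skips the filter.
#' @return A one-set `shift_tbl`.
#' @examples
#' ens <- generate_conformer_ensemble(n_conformers = 5, n_atoms = 4, seed = 2)
#' idx <- tibble::tibble(label = ensemble_atom_labels(ens),
#'                       hybridization = "sp3")
#' std <- calibration_standards(tms_sigma = 186.6, benzene_sigma = 57.3)
#' ensemble_to_shifts(ens, idx, std, set_id = "calc_X")
#' @export
ensemble_to_shifts <- function(ensemble, atom_index, standards,
                               set_id = "calc",
                               temperature = 298.15,
                               energy_unit = c("kcal_mol", "kj_mol", "hartree"),
                               energy_window = 3.0,
                               carbonyl_policy = c("tms", "benzene"),
                               origin = "calculated") {
  energy_unit <- arg_match(energy_unit)
  if (!is.null(energy_window)) {
    ensemble <- energy_window_filter(ensemble, energy_window)
  }
  w <- boltzmann_weights(ensemble, temperature, energy_unit)
  sigma <- average_shieldings(ensemble, w)
  calibrate_multistandard(sigma, atom_index, standards, carbonyl_policy,
                          set_id = set_id, origin = origin)
}

#' Atom labels covered by a conformer ensemble
#'
#' @inheritParams energy_window_filter
#' @return Character vector of atom labels in column order.
#' @export
ensemble_atom_labels <- function(ensemble) ensemble_labels(ensemble)
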