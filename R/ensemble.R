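#' Retain conformers inside a relative-energy window
#'
#' Conformer searches typically save every local minimum within a broad
#' energy band (21 kJ/mol here), but only the major contributors within a
#' narrower window (10 kJ/mol by default) enter the NMR averaging. The
#' boundary is inclusive (`rel_energy_kJmol <= window_kJmol`), so a window
#' of 0 degenerates cleanly to the global minimum alone — the
#' single-conformer mode used when screening method combinations.
#'
#' @param energies Tibble with `conformer_id` and `rel_energy_kJmol`
#'   (relative to the ensemble minimum), or `conformer_id`, `energy`,
#'   `unit`, which is converted first.
#' @param window_kJmol Non-negative window width in kJ/mol (default 10).
#' @return The retained rows, as a tibble of `conformer_id` and
#'   `rel_energy_kJmol`; always includes the global minimum.
#' @examples
#' e <- tibble::tibble(conformer_id = letters[1:4],
#'                     rel_energy_kJmol = c(0, 5, 9.99, 10.01))
#' filter_window(e, 10)
#' @export
filter_window <- function(energies, window_kJmol = 10) {
  if (window_kJmol < 0) abort("invalid window: must be >= 0")
  if (nrow(as_tibble(energies)) == 0) abort("empty ensemble")
  energies <- normalize_energies(energies)
  dplyr::filter(energies, .data$rel_energy_kJmol <= window_kJmol)
}

#' Boltzmann populations of a conformer ensemble
#'
#' Computes the equilibrium population weight of each conformer,
#' \eqn{w_i = e^{-\Delta E_i / RT} / \sum_j e^{-\Delta E_j / RT}}, from
#' relative energies in kJ/mol (converted to J/mol before dividing by
#' \eqn{RT}). Weights are renormalized over the supplied (already
#' window-filtered) subset only. The minimum energy is subtracted before
#' exponentiating, which leaves the weights unchanged but avoids overflow.
#'
#' @inheritParams filter_window
#' @param temperature_K Temperature in kelvin (default 298).
#' @param gas_constant Molar gas constant in J K\eqn{^{-1}} mol\eqn{^{-1}}
#'   (default 8.3145).
#' @return Tibble with `conformer_id`, `rel_energy_kJmol` and `weight`;
#'   weights are strictly positive and sum to 1.
#' @examples
#' boltzmann_weights(tibble::tibble(conformer_id = c("a", "b"),
#'                                  rel_energy_kJmol = c(0, 10)))
#' @export
boltzmann_weights <- function(energies, temperature_K = 298,
                              gas_constant = GAS_CONSTANT_R) {
  if (!is.finite(temperature_K) || temperature_K <= 0) {
    abort("invalid temperature: temperature_K must be > 0")
  }
  if (nrow(as_tibble(energies)) == 0) abort("empty ensemble")
  energies <- normalize_energies(energies)
  de_J <- (energies$rel_energy_kJmol - min(energies$rel_energy_kJmol)) * 1000
  q <- exp(-de_J / (gas_constant * temperature_K))
  dplyr::mutate(energies, weight = q / sum(q))
}

#' Boltzmann-weighted ensemble average of per-atom shieldings
#'
#' Averages each atom's isotropic shielding over conformers with the
#' supplied population weights:
#' \eqn{\sigma_{cal} = \sum_i w_i \, \sigma_i}. With a single conformer of
#' weight 1 this reduces to that conformer's shieldings, the form used
#' during method screening on the global minimum.
#'
#' @param shieldings Tibble with `conformer_id`, `atom_index`, `element`,
#'   `isotropic_shielding_ppm`.
#' @param weights Tibble with `conformer_id` and `weight`, as returned by
#'   [boltzmann_weights()]. Conformers absent from `weights` are dropped;
#'   every retained conformer must supply every atom.
#' @return Tibble with one row per atom: `atom_index`, `element`,
#'   `isotropic_shielding_ppm` (the weighted average).
#' @export
ensemble_average <- function(shieldings, weights) {
  require_columns(shieldings, c("conformer_id", "atom_index", "element",
                                "isotropic_shielding_ppm"), "shieldings")
  require_columns(weights, c("conformer_id", "weight"), "weights")
  kept <- dplyr::semi_join(shieldings, weights, by = "conformer_id")
  if (nrow(kept) == 0) abort("empty ensemble")

  atoms_per_conf <- dplyr::count(kept, .data$conformer_id)
  atoms <- dplyr::distinct(kept, .data$atom_index, .data$element)
  if (anyDuplicated(atoms$atom_index)) {
    abort("assignment inconsistency: an atom_index maps to two elements")
  }
  if (any(atoms_per_conf$n != nrow(atoms)) ||
      nrow(kept) != nrow(atoms) * nrow(atoms_per_conf)) {
    abort("incomplete conformer: retained conformers do not share one atom set")
  }

  w <- weights$weight / sum(weights$weight)
  names(w) <- weights$conformer_id
  kept |>
    dplyr::mutate(w = w[.data$conformer_id]) |>
    dplyr::summarise(
      element = .data$element[1],
      isotropic_shielding_ppm =
        sum(.data$w * .data$isotropic_shielding_ppm) / sum(.data$w),
      .by = "atom_index"
    ) |>
    dplyr::arrange(.data$atom_index)
}

#' Window-filter, weight and average a study in one step
#'
#' Convenience wrapper running [filter_window()], [boltzmann_weights()] and
#' [ensemble_average()] on an [nmr_study()], then averaging equivalent
#' atoms with [group_average()]. `window_kJmol = 0` gives the
#' global-minimum, single-conformer mode used for screening.
#'
#' @param study An `nmr_study`.
#' @param window_kJmol Energy window in kJ/mol (default 10).
#' @param temperature_K,gas_constant Passed to [boltzmann_weights()].
#' @return Tibble with `group_id`, `nucleus`, `delta_exp_ppm` and the
#'   ensemble- and equivalence-averaged `isotropic_shielding_ppm`.
#' @export
boltzmann_shieldings <- function(study, window_kJmol = 10,
                                 temperature_K = 298,
                                 gas_constant = GAS_CONSTANT_R) {
  stopifnot(inherits(study, "nmr_study"))
  w <- study$energies |>
    filter_window(window_kJmol) |>
    boltzmann_weights(temperature_K, gas_constant)
  ensemble_average(study$shieldings, w) |>
    group_average(study$assignments)
}
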