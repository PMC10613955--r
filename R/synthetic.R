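#' Specification for a synthetic shielding study
#'
#' Describes a simulated multi-conformer shielding set with known ground
#' truth, shaped like a real triterpenoid study: experimental shifts come
#' verbatim from the oxime fixture by default (30 carbon groups spanning
#' 15.4-167.2 ppm, or 13 proton groups / 29 protons spanning 0.86-5.12
#' ppm); shieldings follow the linear law
#' \eqn{\sigma = a\,\delta_{exp} + b} plus a conformer-level effect (drawn
#' once per conformer per group, shared by that group's equivalent atoms)
#' and independent atom-level noise; relative energies span a 0-10 kJ/mol
#' window with the global minimum at exactly 0, emulating an ensemble of
#' major contributors left after windowing a broader 21 kJ/mol search pool.
#'
#' The default slope and intercept are arbitrary, plausible generator
#' values (shielding decreasing with shift), not values taken from any
#' fitted method.
#'
#' @param nucleus `"13C"` (default) or `"1H"`.
#' @param assignments Assignment tibble to simulate against; default
#'   [oxime_assignments()] for `nucleus`.
#' @param a,b True slope and intercept of the shielding law. Defaults:
#'   `a = -1.05, b = 186` for 13C; `a = -1.07, b = 31.9` for 1H.
#' @param n_conformers Number of conformers (default 15).
#' @param max_rel_energy_kJmol Upper edge of the relative-energy spread
#'   (default 10).
#' @param conformer_sd Standard deviation (ppm) of the per-conformer,
#'   per-group shielding effect. Defaults: 0.3 (13C), 0.03 (1H).
#' @param atom_noise_sd Standard deviation (ppm) of independent per-atom
#'   noise. Defaults: 0.5 (13C), 0.05 (1H).
#' @return A `generator_spec` list.
#' @seealso [generate_study()]
#' @export
generator_spec <- function(nucleus = c("13C", "1H"), assignments = NULL,
                           a = NULL, b = NULL, n_conformers = 15,
                           max_rel_energy_kJmol = 10,
                           conformer_sd = NULL, atom_noise_sd = NULL) {
  nucleus <- match.arg(nucleus)
  defaults <- list(
    "13C" = list(a = -1.05, b = 186, conformer_sd = 0.3, atom_noise_sd = 0.5),
    "1H" = list(a = -1.07, b = 31.9, conformer_sd = 0.03, atom_noise_sd = 0.05)
  )[[nucleus]]
  spec <- list(
    nucleus = nucleus,
    assignments = assignments %||% oxime_assignments(nucleus),
    a = a %||% defaults$a,
    b = b %||% defaults$b,
    n_conformers = n_conformers,
    max_rel_energy_kJmol = max_rel_energy_kJmol,
    conformer_sd = conformer_sd %||% defaults$conformer_sd,
    atom_noise_sd = atom_noise_sd %||% defaults$atom_noise_sd
  )
  if (spec$a == 0) abort("invalid generator spec: a must be nonzero")
  if (spec$n_conformers < 1) {
    abort("invalid generator spec: n_conformers must be >= 1")
  }
  if (spec$conformer_sd < 0 || spec$atom_noise_sd < 0) {
    abort("invalid generator spec: noise sds must be >= 0")
  }
  if (spec$max_rel_energy_kJmol < 0) {
    abort("invalid generator spec: max_rel_energy_kJmol must be >= 0")
  }
  structure(spec, class = "generator_spec")
}

#' Generate a synthetic study with known ground truth
#'
#' Draws a complete, validated [nmr_study()] from a [generator_spec()],
#' together with the ground truth needed to verify every downstream stage:
#' the true `(a, b)`, the relative energies, the Boltzmann weights those
#' energies imply at 298 K, and the per-conformer per-group effects. The
#' same seed always reproduces the identical bundle.
#'
#' @param spec A `generator_spec` (default: 13C defaults).
#' @param seed Integer seed; required for reproducibility.
#' @return A list with `study` (an `nmr_study`) and `truth` (a list with
#'   `a`, `b`, `energies`, `weights`, `conformer_effects`).
#' @examples
#' sim <- generate_study(generator_spec("13C"), seed = 1)
#' sim$study
#' @export
generate_study <- function(spec = generator_spec(), seed) {
  stopifnot(inherits(spec, "generator_spec"))
  if (missing(seed) || is.null(seed) || is.na(seed)) {
    abort("invalid generator spec: a seed is required")
  }
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))

  asg <- spec$assignments
  flat <- tidyr::unnest(
    asg[c("group_id", "nucleus", "delta_exp_ppm", "atom_indices")],
    "atom_indices"
  ) |>
    dplyr::rename(atom_index = "atom_indices") |>
    dplyr::mutate(element = nucleus_element(.data$nucleus))

  n_conf <- spec$n_conformers
  conf_ids <- sprintf("conf-%02d", seq_len(n_conf))
  rel_e <- c(0, if (n_conf > 1) runif(n_conf - 1, 0, spec$max_rel_energy_kJmol))
  energies <- tibble(conformer_id = conf_ids, rel_energy_kJmol = rel_e)

  effects <- tidyr::expand_grid(conformer_id = conf_ids,
                                group_id = asg$group_id) |>
    dplyr::mutate(effect_ppm = rnorm(dplyr::n(), 0, spec$conformer_sd))

  shieldings <- tidyr::expand_grid(conformer_id = conf_ids,
                                   flat["atom_index"]) |>
    dplyr::left_join(flat, by = "atom_index") |>
    dplyr::left_join(effects, by = c("conformer_id", "group_id")) |>
    dplyr::mutate(
      isotropic_shielding_ppm =
        spec$a * .data$delta_exp_ppm + spec$b + .data$effect_ppm +
        rnorm(dplyr::n(), 0, spec$atom_noise_sd)
    ) |>
    dplyr::select("conformer_id", "atom_index", "element",
                  "isotropic_shielding_ppm")

  study <- nmr_study(shieldings, energies, asg)
  weights <- {
    de_J <- rel_e * 1000
    q <- exp(-de_J / (GAS_CONSTANT_R * 298))
    tibble(conformer_id = conf_ids, weight = q / sum(q))
  }
  list(
    study = study,
    truth = list(a = spec$a, b = spec$b, energies = energies,
                 weights = weights, conformer_effects = effects)
  )
}

#' Experimental assignment tables of the dipterocarpol oxime fixture
#'
#' The packaged worked example: the published 1H/13C assignment lists of a
#' dammarane triterpenoid oxime (30 carbon resonances, and the 29
#' assignable protons encoded as 13 equivalence groups: 8 three-proton
#' methyls — two of which overlap at 1.14 ppm but remain distinct groups —
#' the olefinic H24, diastereotopic H2a/H2b, and the two allylic H23
#' protons as separate one-atom groups). Atom indices are the fixture's own
#' 1-based numbering (carbons 1-30, protons 31-59); assignment of indices
#' to atoms is user input in real studies.
#'
#' @param nucleus `"13C"`, `"1H"`, or `"all"` for both tables bound
#'   together.
#' @return An assignment tibble (see [nmr_study()]).
#' @examples
#' oxime_assignments("13C")
#' dplyr::summarise(
#'   tidyr::unnest(oxime_assignments("1H"), atom_indices),
#'   n_protons = dplyr::n()
#' )
#' @export
oxime_assignments <- function(nucleus = c("13C", "1H", "all")) {
  nucleus <- match.arg(nucleus)
  files <- c(
    "13C" = "oxime1_assignments_13C.csv",
    "1H" = "oxime1_assignments_1H.csv"
  )
  want <- if (nucleus == "all") names(files) else nucleus
  purrr::map(files[want], function(f) {
    read_assignments(system.file("extdata", f, package = "shiftscreen",
                                 mustWork = TRUE))
  }) |>
    dplyr::bind_rows()
}

#' Published screening and ensemble metrics for the oxime fixture
#'
#' `oxime_screen_metrics()` returns the published single-conformer
#' screening grid for the six best-performing functionals per nucleus
#' (11 basis sets each; \eqn{r^2} and RMSE per cell).
#' `oxime_ensemble_metrics()` returns the published Boltzmann-averaged
#' results of the six selected combinations per nucleus (\eqn{r^2}, MAE,
#' RMSE, maximum absolute deviation). Both carry `range_ppm`, the spread of
#' the corresponding experimental shift list, so percentage-of-range forms
#' can be computed. Feed either into [screen_from_metrics()] to reproduce
#' rankings and best-per-functional selections.
#'
#' @param nucleus `"13C"` or `"1H"`.
#' @return A tibble of per-method metrics.
#' @examples
#' screen_from_metrics(oxime_screen_metrics("13C"), "13C")
#' @export
oxime_screen_metrics <- function(nucleus = c("13C", "1H")) {
  nucleus <- match.arg(nucleus)
  oxime_metrics_file(sprintf("oxime1_screen_%s.csv", nucleus), nucleus)
}

#' @rdname oxime_screen_metrics
#' @export
oxime_ensemble_metrics <- function(nucleus = c("13C", "1H")) {
  nucleus <- match.arg(nucleus)
  oxime_metrics_file(sprintf("oxime1_ensemble_%s.csv", nucleus), nucleus)
}

# internal: read a packaged metrics table and attach the experimental range
oxime_metrics_file <- function(file, nucleus) {
  df <- readr::read_csv(
    system.file("extdata", file, package = "shiftscreen", mustWork = TRUE),
    show_col_types = FALSE, progress = FALSE
  )
  delta <- oxime_assignments(nucleus)$delta_exp_ppm
  dplyr::mutate(as_tibble(df),
                nucleus = nucleus,
                range_ppm = max(delta) - min(delta))
}
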