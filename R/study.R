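#' Nucleus labels and their element symbols
#'
#' The pipeline handles two nucleus types: `"1H"` (proton) and `"13C"`
#' (carbon-13). Every equivalence group, scaling fit and metrics report is
#' tagged with one of them.
#'
#' @param nucleus Character vector of nucleus labels.
#' @return `nucleus_element()` returns the element symbol ("H" or "C") for
#'   each label; `check_nucleus()` returns the validated label.
#' @examples
#' nucleus_element(c("1H", "13C"))
#' @export
nucleus_element <- function(nucleus) {
  check_nucleus(nucleus)
  c("1H" = "H", "13C" = "C")[nucleus] |> unname()
}

#' @rdname nucleus_element
#' @export
check_nucleus <- function(nucleus) {
  bad <- setdiff(unique(nucleus), c("1H", "13C"))
  if (length(bad) > 0) {
    abort(paste0(
      "assignment inconsistency: unknown nucleus ",
      paste0("'", bad, "'", collapse = ", "),
      " (must be '1H' or '13C')"
    ))
  }
  nucleus
}

#' Assemble and validate an NMR study bundle
#'
#' An `nmr_study` ties together the three tables a shift-prediction run
#' needs: per-conformer per-atom isotropic shieldings, per-conformer
#' energies, and the assignment table mapping equivalence groups of atoms to
#' experimental shifts. Construction validates the bundle: every atom
#' referenced by any equivalence group must be present, with the element
#' implied by the group's nucleus, in every conformer; group ids must be
#' unique; energies must cover exactly the conformers that have shieldings.
#'
#' Energies may arrive in hartree or kJ/mol; they are converted to kJ/mol
#' (1 hartree = 2625.49964 kJ/mol) and immediately re-expressed relative to
#' the ensemble minimum, so the stored `rel_energy_kJmol` always has minimum
#' exactly 0 and absolute offsets never propagate downstream.
#'
#' @param shieldings Tibble with columns `conformer_id`, `atom_index`,
#'   `element`, `isotropic_shielding_ppm`.
#' @param energies Tibble with columns `conformer_id`, `energy`, `unit`
#'   (`"hartree"` or `"kJ/mol"`), or with a precomputed `rel_energy_kJmol`
#'   column.
#' @param assignments Tibble with columns `group_id`, `nucleus`,
#'   `atom_indices` (list-column of 1-based integer vectors), and
#'   `delta_exp_ppm`, as returned by [read_assignments()] or
#'   [oxime_assignments()].
#' @return An object of class `nmr_study`: a list with elements
#'   `shieldings`, `energies` (relative kJ/mol) and `assignments`.
#' @seealso [read_study()], [generate_study()], [validate_study()]
#' @export
nmr_study <- function(shieldings, energies, assignments) {
  shieldings <- as_tibble(shieldings)
  energies <- as_tibble(energies)
  assignments <- as_tibble(assignments)

  require_columns(shieldings, c("conformer_id", "atom_index", "element",
                                "isotropic_shielding_ppm"), "shieldings")
  require_columns(assignments, c("group_id", "nucleus", "atom_indices",
                                 "delta_exp_ppm"), "assignments")

  if (nrow(shieldings) == 0 || nrow(assignments) == 0) {
    abort("empty study: shieldings and assignments must be nonempty")
  }
  if (anyNA(shieldings$isotropic_shielding_ppm) ||
      any(!is.finite(shieldings$isotropic_shielding_ppm))) {
    abort("format error: non-finite isotropic_shielding_ppm in shieldings")
  }
  if (anyDuplicated(shieldings[c("conformer_id", "atom_index")])) {
    abort("format error: duplicate (conformer_id, atom_index) in shieldings")
  }

  energies <- normalize_energies(energies)
  sh_ids <- unique(shieldings$conformer_id)
  if (!setequal(energies$conformer_id, sh_ids)) {
    missing <- setdiff(sh_ids, energies$conformer_id)
    extra <- setdiff(energies$conformer_id, sh_ids)
    abort(paste0(
      "format error: energies and shieldings disagree on conformers",
      if (length(missing)) paste0("; missing energies for ",
                                  paste(missing, collapse = ", ")),
      if (length(extra)) paste0("; energies for unknown conformers ",
                                paste(extra, collapse = ", "))
    ))
  }

  study <- structure(
    list(shieldings = shieldings, energies = energies,
         assignments = assignments),
    class = "nmr_study"
  )
  validate_study(study)
}

#' Validate an assembled study bundle
#'
#' Checks the cross-table invariants of an [nmr_study()]: unique group ids,
#' every group atom present in every conformer, and element/nucleus
#' consistency. Returns the bundle invisibly so it can sit inside a pipe.
#'
#' @param study An `nmr_study` object.
#' @return The validated `nmr_study`, invisibly.
#' @export
validate_study <- function(study) {
  stopifnot(inherits(study, "nmr_study"))
  asg <- study$assignments
  check_nucleus(asg$nucleus)

  if (anyDuplicated(asg$group_id)) {
    dup <- unique(asg$group_id[duplicated(asg$group_id)])
    abort(paste0("duplicate group: ", paste(dup, collapse = ", ")))
  }
  n_atoms <- lengths(asg$atom_indices)
  if (any(n_atoms == 0)) {
    abort("assignment inconsistency: empty atom_indices")
  }
  if (any(vapply(asg$atom_indices, anyDuplicated, 0L) > 0)) {
    abort("assignment inconsistency: duplicated atom within a group")
  }
  flat <- tidyr::unnest(
    asg[c("group_id", "nucleus", "atom_indices")],
    "atom_indices"
  )
  if (any(flat$atom_indices < 1)) {
    abort("assignment inconsistency: atom indices must be 1-based (>= 1)")
  }

  sh <- study$shieldings
  for (cid in unique(sh$conformer_id)) {
    conf <- sh[sh$conformer_id == cid, ]
    hit <- match(flat$atom_indices, conf$atom_index)
    if (anyNA(hit)) {
      miss <- flat$atom_indices[is.na(hit)]
      abort(paste0("incomplete conformer: ", cid, " is missing atom(s) ",
                   paste(unique(miss), collapse = ", ")))
    }
    want <- nucleus_element(flat$nucleus)
    got <- conf$element[hit]
    if (any(got != want)) {
      i <- which(got != want)[1]
      abort(paste0(
        "assignment inconsistency: group ", flat$group_id[i], " (",
        flat$nucleus[i], ") references atom ", flat$atom_indices[i],
        " which is ", got[i], " in conformer ", cid
      ))
    }
  }
  invisible(study)
}

#' @export
print.nmr_study <- function(x, ...) {
  n_conf <- dplyr::n_distinct(x$shieldings$conformer_id)
  counts <- table(x$assignments$nucleus)
  cat("<nmr_study> ", n_conf, " conformer(s); ",
      nrow(x$assignments), " equivalence group(s) [",
      paste(names(counts), counts, sep = ": ", collapse = ", "),
      "]\n", sep = "")
  invisible(x)
}

#' Average per-atom values over equivalence groups
#'
#' Nuclei that are equivalent on the NMR timescale (for example a methyl
#' group's three protons under fast rotation) give a single observed signal,
#' so computed per-atom values are averaged arithmetically within each
#' equivalence group before they are compared with experiment.
#'
#' @param per_atom Tibble of per-atom values with an `atom_index` column and
#'   the value column named by `value`; an optional `conformer_id` column
#'   keeps conformers separate.
#' @param assignments Assignment tibble (see [nmr_study()]).
#' @param value Name of the value column to average (default
#'   `"isotropic_shielding_ppm"`).
#' @return A tibble with one row per group (per conformer, if
#'   `conformer_id` is present): `group_id`, `nucleus`, `delta_exp_ppm`,
#'   and the averaged value column.
#' @examples
#' asg <- tibble::tibble(
#'   group_id = "Me1", nucleus = "1H",
#'   atom_indices = list(1:3), delta_exp_ppm = 1.05
#' )
#' vals <- tibble::tibble(atom_index = 1:3,
#'                        isotropic_shielding_ppm = c(29, 30, 31))
#' group_average(vals, asg)
#' @export
group_average <- function(per_atom, assignments,
                          value = "isotropic_shielding_ppm") {
  per_atom <- as_tibble(per_atom)
  require_columns(per_atom, c("atom_index", value), "per_atom")
  require_columns(assignments, c("group_id", "nucleus", "atom_indices",
                                 "delta_exp_ppm"), "assignments")

  flat <- tidyr::unnest(
    assignments[c("group_id", "nucleus", "delta_exp_ppm", "atom_indices")],
    "atom_indices"
  ) |>
    dplyr::rename(atom_index = "atom_indices")

  by_conf <- "conformer_id" %in% names(per_atom)
  joined <- dplyr::inner_join(flat, per_atom, by = "atom_index",
                              relationship = "many-to-many")
  keys <- c(if (by_conf) "conformer_id", "group_id")
  expected <- if (by_conf) {
    nrow(flat) * dplyr::n_distinct(per_atom$conformer_id)
  } else {
    nrow(flat)
  }
  if (nrow(joined) != expected) {
    abort("incomplete conformer: per-atom values missing for some group atoms")
  }
  joined |>
    dplyr::summarise(
      nucleus = .data$nucleus[1],
      delta_exp_ppm = .data$delta_exp_ppm[1],
      "{value}" := mean(.data[[value]]),
      .by = dplyr::all_of(keys)
    )
}

# internal: column-presence check with a "format error" message
require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(paste0("format error: ", what, " is missing column(s) ",
                 paste(missing, collapse = ", ")))
  }
  invisible(df)
}

# internal: accept (conformer_id, energy, unit) or (conformer_id,
# rel_energy_kJmol); return tibble(conformer_id, rel_energy_kJmol) with
# minimum exactly 0
normalize_energies <- function(energies) {
  energies <- as_tibble(energies)
  if (!"conformer_id" %in% names(energies)) {
    abort("format error: energies is missing column(s) conformer_id")
  }
  if (anyDuplicated(energies$conformer_id)) {
    abort("format error: duplicate conformer_id in energies")
  }
  if ("rel_energy_kJmol" %in% names(energies)) {
    e_kj <- energies$rel_energy_kJmol
  } else {
    require_columns(energies, c("energy", "unit"), "energies")
    bad <- setdiff(unique(energies$unit), c("hartree", "kJ/mol"))
    if (length(bad) > 0) {
      abort(paste0("format error: unsupported unit ",
                   paste0("'", bad, "'", collapse = ", ")))
    }
    e_kj <- ifelse(energies$unit == "hartree",
                   energies$energy * HARTREE_KJ_MOL,
                   energies$energy)
  }
  if (anyNA(e_kj) || any(!is.finite(e_kj))) {
    abort("format error: non-finite energy")
  }
  tibble(conformer_id = energies$conformer_id,
         rel_energy_kJmol = e_kj - min(e_kj))
}
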