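#' Parse a quantum-chemistry log for shieldings and the final SCF energy
#'
#' Extracts GIAO isotropic shieldings and the single-point energy from a
#' text log in the widely used layout where a "Magnetic shielding tensor
#' (ppm)" section contains one `<index> <element> Isotropic = <value>` line
#' per atom, and energies appear on `SCF Done:` lines in hartree. When a job
#' prints several energies (e.g. optimization followed by a single point)
#' the last one wins. Engines with other layouts are supported through the
#' tidy interchange tables instead (see [read_study()]).
#'
#' @param file Path to a log file, or a character vector of its lines.
#' @param conformer_id Identifier for the conformer this log describes;
#'   defaults to the file name without extension.
#' @return A list with `shieldings` (tibble: `conformer_id`, `atom_index`,
#'   `element`, `isotropic_shielding_ppm`) and `energies` (tibble:
#'   `conformer_id`, `energy`, `unit`; `energy` is `NA` when no energy line
#'   is present, with a warning).
#' @examples
#' log <- c(
#'   " SCF Done:  E(RB3LYP) =  -1330.30176520     A.U. after   12 cycles",
#'   " Magnetic shielding tensor (ppm):",
#'   "      1  C    Isotropic =   187.9000   Anisotropy =    20.1",
#'   "      2  H    Isotropic =    31.1000   Anisotropy =     8.3")
#' parse_engine_log(log, conformer_id = "conf-01")
#' @export
parse_engine_log <- function(file, conformer_id = NULL) {
  if (length(file) == 1 && !grepl("\n", file) && file.exists(file)) {
    if (is.null(conformer_id)) {
      conformer_id <- sub("\\.[^.]*$", "", basename(file))
    }
    lines <- readr::read_lines(file)
  } else {
    lines <- unlist(strsplit(file, "\r?\n"))
    if (is.null(conformer_id)) conformer_id <- "conformer"
  }
  lines <- sub("\r$", "", lines)

  num <- "[-+]?[0-9]*\\.?[0-9]+(?:[eEdD][-+]?[0-9]+)?"

  energy_hits <- stringr::str_match(
    lines, paste0("^\\s*SCF Done:\\s+E\\([^)]*\\)\\s*=\\s*(", num, ")")
  )[, 2]
  energy_vals <- as.numeric(gsub("[dD]", "e", energy_hits[!is.na(energy_hits)]))
  energy <- if (length(energy_vals)) energy_vals[length(energy_vals)] else NA_real_
  if (is.na(energy)) {
    warn(paste0("no energy line found for conformer ", conformer_id))
  }

  in_section <- FALSE
  rows <- list()
  atom_re <- paste0("^\\s*(\\d+)\\s+([A-Za-z]{1,2})\\s+Isotropic\\s*=\\s*(",
                    num, ")")
  for (line in lines) {
    if (grepl("Magnetic shielding tensor \\(ppm\\)", line)) {
      in_section <- TRUE
      next
    }
    if (in_section) {
      m <- stringr::str_match(line, atom_re)
      if (!is.na(m[1, 1])) {
        rows[[length(rows) + 1]] <- list(
          atom_index = as.integer(m[1, 2]),
          element = m[1, 3],
          isotropic_shielding_ppm = as.numeric(gsub("[dD]", "e", m[1, 4]))
        )
      } else if (!grepl("^\\s*$", line) &&
                 !grepl("Isotropic|Anisotropy|Eigenvalues|[XYZ][XYZ]=",
                        line)) {
        in_section <- FALSE
      }
    }
  }
  shieldings <- dplyr::bind_rows(rows)
  if (nrow(shieldings) == 0) {
    warn(paste0("no magnetic shielding section found for conformer ",
                conformer_id))
    shieldings <- tibble(atom_index = integer(), element = character(),
                         isotropic_shielding_ppm = double())
  }
  if (anyDuplicated(shieldings$atom_index)) {
    abort(paste0("malformed log: duplicate atom index in shielding block of ",
                 conformer_id))
  }
  list(
    shieldings = dplyr::bind_cols(
      tibble(conformer_id = rep(conformer_id, nrow(shieldings))), shieldings
    ),
    energies = tibble(conformer_id = conformer_id, energy = energy,
                      unit = "hartree")
  )
}

#' Parse several logs into one shielding and one energy table
#'
#' @param files Character vector of log-file paths, one conformer each.
#' @param conformer_ids Optional identifiers; default file names.
#' @return A list with combined `shieldings` and `energies` tibbles.
#' @export
parse_engine_logs <- function(files, conformer_ids = NULL) {
  if (is.null(conformer_ids)) {
    conformer_ids <- sub("\\.[^.]*$", "", basename(files))
  }
  parsed <- purrr::map2(files, conformer_ids, parse_engine_log)
  list(
    shieldings = purrr::map(parsed, "shieldings") |> dplyr::bind_rows(),
    energies = purrr::map(parsed, "energies") |> dplyr::bind_rows()
  )
}

#' Read the tidy interchange tables
#'
#' The engine-agnostic interchange format is three delimited text files:
#' shieldings (`conformer_id,atom_index,element,isotropic_shielding_ppm`),
#' energies (`conformer_id,energy,unit` with unit `hartree` or `kJ/mol`),
#' and assignments (`group_id,nucleus,atom_indices,delta_exp_ppm` with
#' semicolon-separated 1-based atom indices and nucleus `1H` or `13C`).
#'
#' @param shieldings_file,energies_file,assignments_file Paths to the three
#'   CSV files.
#' @return A validated [nmr_study()] bundle.
#' @export
read_study <- function(shieldings_file, energies_file, assignments_file) {
  nmr_study(
    shieldings = read_shieldings(shieldings_file),
    energies = read_energies(energies_file),
    assignments = read_assignments(assignments_file)
  )
}

#' @rdname read_study
#' @export
read_shieldings <- function(shieldings_file) {
  df <- read_checked(shieldings_file,
                     c("conformer_id", "atom_index", "element",
                       "isotropic_shielding_ppm"))
  df$atom_index <- as.integer(df$atom_index)
  df$isotropic_shielding_ppm <- as.numeric(df$isotropic_shielding_ppm)
  df
}

#' @rdname read_study
#' @export
read_energies <- function(energies_file) {
  df <- read_checked(energies_file, c("conformer_id", "energy", "unit"))
  df$energy <- as.numeric(df$energy)
  bad <- setdiff(unique(df$unit), c("hartree", "kJ/mol"))
  if (length(bad) > 0) {
    abort(paste0("format error: unsupported unit ",
                 paste0("'", bad, "'", collapse = ", "),
                 " in ", energies_file))
  }
  df
}

#' @rdname read_study
#' @export
read_assignments <- function(assignments_file) {
  df <- read_checked(assignments_file,
                     c("group_id", "nucleus", "atom_indices",
                       "delta_exp_ppm"))
  idx <- strsplit(as.character(df$atom_indices), ";", fixed = TRUE) |>
    purrr::map(function(x) {
      x <- trimws(x)
      i <- suppressWarnings(as.integer(x))
      if (anyNA(i)) {
        abort(paste0("format error: non-integer atom index in column ",
                     "atom_indices of ", assignments_file))
      }
      i
    })
  tibble(
    group_id = as.character(df$group_id),
    nucleus = check_nucleus(as.character(df$nucleus)),
    atom_indices = idx,
    delta_exp_ppm = as.numeric(df$delta_exp_ppm)
  )
}

#' Write a study bundle as interchange tables
#'
#' Inverse of [read_study()]: writes the three CSV files so that reading
#' them back reproduces the bundle exactly (energies are written as
#' relative kJ/mol, the form the bundle stores).
#'
#' @param study An `nmr_study`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named character vector of the three file paths.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "nmr_study"))
  if (nrow(study$shieldings) == 0) abort("empty study")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    shieldings = file.path(dir, "shieldings.csv"),
    energies = file.path(dir, "energies.csv"),
    assignments = file.path(dir, "assignments.csv")
  )
  readr::write_csv(study$shieldings, paths[["shieldings"]])
  readr::write_csv(
    tibble(conformer_id = study$energies$conformer_id,
           energy = study$energies$rel_energy_kJmol,
           unit = "kJ/mol"),
    paths[["energies"]]
  )
  asg <- study$assignments
  readr::write_csv(
    tibble(
      group_id = asg$group_id,
      nucleus = asg$nucleus,
      atom_indices = purrr::map_chr(asg$atom_indices, paste, collapse = ";"),
      delta_exp_ppm = asg$delta_exp_ppm
    ),
    paths[["assignments"]]
  )
  invisible(paths)
}

# internal: read a delimited file and fail with a format error naming the
# missing columns
read_checked <- function(path, cols) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(paste0("format error: ", path, " is missing column(s) ",
                 paste(missing, collapse = ", ")))
  }
  as_tibble(df)
}
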