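# NOESY cross-peak volumes -> calibrated distances -> strength classes ->
# flat-bottom distance-restraint bounds, with pseudoatom and heavy-atom
# corrections, plus Gromacs-style restraint export.
#
# Unit boundary: calibrated distances, classification thresholds and
# pseudoatom corrections are in Angstrom (the NMR convention); restraint
# bounds r0/r1/r2 are stored in nm (the MD-engine convention).

#' Default NOE pipeline configuration
#'
#' `ref_distance` is the geminal methylene proton separation used for
#' volume calibration (1.78 A, the ideal H-C-H geometry). Pseudoatom
#' corrections are per pseudoatom end, in Angstrom, following the usual
#' upper-bound additions for equivalent or non-stereoassigned protons.
#' `heavy_atom_offset` is added when a restraint must fall back from a
#' proton to its bound heavy atom (one typical C-H bond length, 1.1 A).
#'
#' @return A list of defaults, all overridable in the pipeline functions.
#' @export
noe_defaults <- function() {
  list(
    ref_distance = 1.78,
    pseudoatom_corrections = c(methylene = 1.0, methyl = 1.0, aromatic = 2.0),
    heavy_atom_offset = 1.1, # Angstrom
    class_bounds_nm = tibble(
      strength = c("strong", "medium", "weak", "very_weak"),
      r0 = c(0.18, 0.18, 0.18, 0.55),
      r1 = c(0.25, 0.33, 0.55, 10),
      r2 = c(0.38, 0.50, 0.83, 10)
    )
  )
}

#' Calibrate NOE cross-peak volumes into distances
#'
#' r = ref_distance * (ref_volume / volume)^(1/6): the cross-peak volume
#' scales as the inverse sixth power of the inter-proton distance, so a
#' peak 64-fold weaker than the reference lies at twice the reference
#' distance. Strictly decreasing in volume; exact at the reference.
#'
#' @param peaks Data frame with a `volume` column (> 0); typically also
#'   `res_a`, `atom_a`, `res_b`, `atom_b`.
#' @param ref_volume Reference volume (> 0), e.g. the average volume of
#'   resolved geminal methylene cross-peaks.
#' @param ref_distance Reference distance in Angstrom.
#' @return Input tibble with an added `distance` column (Angstrom).
#' @export
calibrate_distances <- function(peaks, ref_volume,
                                ref_distance = noe_defaults()$ref_distance) {
  stopifnot("volume" %in% names(peaks))
  if (ref_volume <= 0 || ref_distance <= 0) {
    abort("ref_volume and ref_distance must be > 0")
  }
  if (any(peaks$volume <= 0)) abort("all peak volumes must be > 0")
  as_tibble(peaks) %>%
    mutate(distance = ref_distance * (ref_volume / .data$volume)^(1 / 6))
}

#' Classify an NOE upper-bound distance into a restraint strength
#'
#' Wuthrich-style nested classes on the upper bound (Angstrom):
#' strong <= 2.8, medium <= 3.8, weak <= 5.0, else very weak. Upper edges
#' are inclusive so ties break deterministically.
#'
#' @param r_upper Upper-bound distance(s), Angstrom.
#' @return Character vector of classes (`strong`, `medium`, `weak`,
#'   `very_weak`).
#' @export
#' @examples
#' classify_strength(c(2.6, 2.8, 3.0, 5.4))
classify_strength <- function(r_upper) {
  if (any(r_upper <= 0)) abort("r_upper must be > 0")
  dplyr::case_when(
    r_upper <= 2.8 ~ "strong",
    r_upper <= 3.8 ~ "medium",
    r_upper <= 5.0 ~ "weak",
    TRUE ~ "very_weak"
  )
}

# Methyl-bearing pseudoatoms by (residue one-letter, pseudoatom name);
# aromatic ring pseudoatoms by residue.
METHYL_PSEUDO <- c("A.QB", "V.QG", "V.QG1", "V.QG2", "L.QD", "L.QD1",
                   "L.QD2", "I.QG2", "I.QD1", "T.QG2", "M.QE")
AROMATIC_RES <- c("F", "Y", "W", "H")

#' Per-end pseudoatom upper-bound correction
#'
#' Atom names beginning with `Q` (or ending in `#`/`*`) denote pseudoatoms
#' standing for groups of equivalent or non-stereoassigned protons. The
#' correction depends on the group type: methyl and methylene +1.0 A,
#' aromatic ring +2.0 A by default. Non-pseudoatom names get 0.
#'
#' @param atom Atom name(s), e.g. `"HA"`, `"QB"`, `"QD"`.
#' @param residue Parent residue one-letter code(s) (used to tell methyl
#'   and aromatic pseudoatoms apart).
#' @param corrections Named vector, see [noe_defaults()].
#' @return Correction(s) in Angstrom.
#' @export
pseudoatom_correction <- function(atom, residue,
                                  corrections = noe_defaults()$pseudoatom_corrections) {
  stopifnot(length(atom) == length(residue))
  purrr::map2_dbl(atom, residue, function(a, res) {
    is_pseudo <- grepl("^Q", a) || grepl("[#*]$", a)
    if (!is_pseudo) return(0)
    key <- paste0(res, ".", sub("[#*]$", "", a))
    if (key %in% METHYL_PSEUDO) {
      corrections[["methyl"]]
    } else if (res %in% AROMATIC_RES && grepl("^Q[DEZR]", a)) {
      corrections[["aromatic"]]
    } else {
      corrections[["methylene"]]
    }
  })
}

#' Build flat-bottom restraint bounds for a strength class
#'
#' Maps each class to its (r0, r1) interval in nm and sets the outer bound
#' r2 as a 50% increase over r1, rounded to 2 decimals in nm (0.25 -> 0.38,
#' 0.33 -> 0.5, 0.55 -> 0.83) -- except very weak restraints, where r1 and
#' r2 are both 10 nm, an effectively unbounded upper limit for a short
#' peptide. When no hydrogen is available and the restraint falls back to
#' the bound heavy atom, 1.1 A (0.11 nm) is added to the bounds and the
#' fallback flagged.
#'
#' @param strength Class vector (`strong`, `medium`, `weak`, `very_weak`).
#' @param hydrogen_available Logical vector (recycled); `FALSE` applies the
#'   heavy-atom offset.
#' @param config See [noe_defaults()].
#' @return Tibble with `strength`, `r0`, `r1`, `r2` (nm),
#'   `heavy_atom_offset_applied`.
#' @export
#' @examples
#' build_restraint("strong")                  # 0.18 0.25 0.38
#' build_restraint("weak", hydrogen_available = FALSE)
build_restraint <- function(strength, hydrogen_available = TRUE,
                            config = noe_defaults()) {
  bounds <- config$class_bounds_nm
  bad <- setdiff(strength, bounds$strength)
  if (length(bad)) abort(sprintf("unknown strength class: %s", paste(bad, collapse = ", ")))
  hydrogen_available <- rep_len(hydrogen_available, length(strength))
  out <- tibble(strength = strength,
                heavy_atom_offset_applied = !hydrogen_available) %>%
    left_join(bounds, by = "strength") %>%
    mutate(r2 = ifelse(.data$strength == "very_weak", .data$r2,
                       round(1.5 * .data$r1, 2)))
  off <- config$heavy_atom_offset / 10 # Angstrom -> nm
  out %>%
    mutate(
      r0 = .data$r0 + ifelse(.data$heavy_atom_offset_applied, off, 0),
      r1 = ifelse(.data$strength == "very_weak", .data$r1,
                  .data$r1 + ifelse(.data$heavy_atom_offset_applied, off, 0)),
      r2 = ifelse(.data$strength == "very_weak", .data$r2,
                  .data$r2 + ifelse(.data$heavy_atom_offset_applied, off, 0))
    ) %>%
    select("strength", "r0", "r1", "r2", "heavy_atom_offset_applied")
}

residue_range_class <- function(sep) {
  dplyr::case_when(
    sep == 0 ~ "intra",
    sep == 1 ~ "sequential",
    sep <= 4 ~ "medium",
    TRUE ~ "long"
  )
}

#' Full NOE-to-restraint pipeline
#'
#' Chains calibration, pseudoatom correction of the upper bound, strength
#' classification and bound construction, preserving peak order. The
#' calibration reference volume is either passed explicitly or computed as
#' the mean volume of rows flagged `is_reference` (the resolved geminal
#' methylene cross-peaks).
#'
#' @param peaks Data frame with `res_a`, `atom_a`, `res_b`, `atom_b`,
#'   `volume`; optional `is_reference` (logical) and `hydrogen_available`.
#' @param p The `modified_peptide` topology (for pseudoatom typing).
#' @param ref_volume Reference volume; `NULL` uses the `is_reference` rows.
#' @param config See [noe_defaults()].
#' @return Tibble of restraints: peak columns plus `distance`,
#'   `correction`, `r_upper` (Angstrom), `range_class`, `strength`, `r0`,
#'   `r1`, `r2` (nm), `heavy_atom_offset_applied`.
#' @export
restraint_table <- function(peaks, p, ref_volume = NULL, config = noe_defaults()) {
  stopifnot(inherits(p, "modified_peptide"))
  peaks <- as_tibble(peaks)
  if (!nrow(peaks)) {
    return(tibble(res_a = integer(), atom_a = character(), res_b = integer(),
                  atom_b = character(), volume = double(), distance = double(),
                  correction = double(), r_upper = double(),
                  range_class = character(), strength = character(),
                  r0 = double(), r1 = double(), r2 = double(),
                  heavy_atom_offset_applied = logical()))
  }
  if (is.null(ref_volume)) {
    if (!"is_reference" %in% names(peaks) || !any(peaks$is_reference)) {
      abort("ref_volume not given and no peaks flagged is_reference")
    }
    ref_volume <- mean(peaks$volume[peaks$is_reference])
  }
  if (!"hydrogen_available" %in% names(peaks)) peaks$hydrogen_available <- TRUE

  res_code <- setNames(p$one_letter, p$index)
  out <- calibrate_distances(peaks, ref_volume, config$ref_distance) %>%
    mutate(
      correction =
        pseudoatom_correction(.data$atom_a, res_code[as.character(.data$res_a)],
                              config$pseudoatom_corrections) +
        pseudoatom_correction(.data$atom_b, res_code[as.character(.data$res_b)],
                              config$pseudoatom_corrections),
      r_upper = .data$distance + .data$correction,
      range_class = residue_range_class(abs(.data$res_a - .data$res_b)),
      strength = classify_strength(.data$r_upper)
    )
  dplyr::bind_cols(
    select(out, -dplyr::any_of(c("is_reference", "hydrogen_available"))),
    select(build_restraint(out$strength, out$hydrogen_available, config), -"strength")
  )
}

#' Write restraints as a Gromacs distance-restraints topology block
#'
#' Emits a `[ distance_restraints ]` include block with fixed-width columns
#' `ai aj type index type' low up1 up2 fac`, where low/up1/up2 are r0/r1/r2
#' in nm. Atom indices come from `atom_map`; if omitted, a deterministic
#' map is built from the restraints' atoms in order of first appearance
#' (replica fan-out and topology merging are the engine's job).
#'
#' @param restraints Output of [restraint_table()].
#' @param path Output file; `NULL` returns the lines invisibly printed.
#' @param atom_map Optional tibble (`res`, `atom`, `index`).
#' @param fac Force-constant scaling factor column (default 1.0).
#' @return The formatted lines, invisibly.
#' @export
write_gromacs_restraints <- function(restraints, path = NULL, atom_map = NULL, fac = 1.0) {
  atoms <- tibble(res = c(restraints$res_a, restraints$res_b),
                  atom = c(restraints$atom_a, restraints$atom_b))
  if (is.null(atom_map)) {
    atom_map <- distinct(atoms) %>% mutate(index = dplyr::row_number())
  }
  key <- function(res, atom) paste(res, atom, sep = "/")
  idx <- setNames(atom_map$index, key(atom_map$res, atom_map$atom))
  ai <- idx[key(restraints$res_a, restraints$atom_a)]
  aj <- idx[key(restraints$res_b, restraints$atom_b)]
  if (anyNA(ai) || anyNA(aj)) abort("atom_map does not cover all restraint atoms")
  lines <- c(
    "[ distance_restraints ]",
    ";   ai     aj  type  index  type'      low      up1      up2    fac",
    sprintf("%6d %6d %5d %6d %6d %8.3f %8.3f %8.3f %6.1f",
            ai, aj, 1L, seq_len(nrow(restraints)) - 1L, 1L,
            restraints$r0, restraints$r1, restraints$r2, fac)
  )
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Write restraints as a generic TSV
#'
#' @param restraints Output of [restraint_table()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_restraint_tsv <- function(restraints, path) {
  readr::write_tsv(restraints, path)
  invisible(path)
}

#' Read an NOE peak table
#'
#' TSV columns `res_a`, `atom_a`, `res_b`, `atom_b`, `volume`, plus any
#' annotation columns (`is_reference`, `hydrogen_available`, `discard`).
#' Rows flagged `discard` (overlapped resonances annotated upstream) are
#' dropped.
#'
#' @param path File path.
#' @return Tibble.
#' @export
read_noe_peaks <- function(path) {
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  if ("discard" %in% names(df)) df <- filter(df, !.data$discard)
  df
}
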