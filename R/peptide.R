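# Sequence grammar, average masses and formal charges for PTM-bearing
# peptides (citrulline, homocitrulline, acetyl-lysine).

# Average residue masses (Da), standard 20 amino acids.
AA_AVERAGE_MASS <- c(
  G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167, V = 99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132
)

#' Default mass configuration for peptide mass computation
#'
#' Average (not monoisotopic) masses throughout, because calculated ESI-MS
#' values for intact peptides follow average-mass arithmetic. The PTM deltas
#' come from the elemental change each modification makes: citrullination
#' swaps NH for O on the arginine side chain (+0.984 Da), carbamylation adds
#' HNCO to lysine (+43.025 Da), acetylation adds C2H2O (+42.037 Da). The
#' N-biotinyl-NH-(PEG)2 acyl cap contribution (net mass added on acylation,
#' i.e. reagent mass minus water) defaults to 543.68 Da, back-derived from
#' the calculated mass of the unmodified capped epitope; it is exposed here
#' precisely because the reagent's elemental formula is not part of the
#' sequence grammar.
#'
#' @return A list with elements `residues` (named numeric, Da), `ptm`
#'   (named numeric deltas, Da), `water` (Da), `amide_cap_delta` (Da, change
#'   from free-acid to carboxamide C terminus) and `biotinyl_peg2_acyl` (Da).
#' @export
#' @examples
#' ptm_mass_defaults()$ptm
ptm_mass_defaults <- function() {
  list(
    residues = AA_AVERAGE_MASS,
    ptm = c(none = 0, Cit = 0.984, hCit = 43.025, KAc = 42.037),
    water = 18.0153,
    amide_cap_delta = -0.9848,
    biotinyl_peg2_acyl = 543.68
  )
}

BIOTIN_PREFIX_RE <- "^Biotinyl-PEG_?2_?-"

#' Parse a PTM-bearing peptide sequence string
#'
#' Accepts one-letter amino-acid codes with inline multi-letter tokens
#' `Cit` (citrulline, replacing Arg), `hCit` (homocitrulline, replacing Lys)
#' and `K(Ac)` (acetyl-lysine), and an optional `Biotinyl-PEG2-` N-terminal
#' cap prefix. Each parsed residue records its parent one-letter code, so
#' the chemical placement invariants (Cit on R; hCit and K(Ac) on K) hold by
#' construction.
#'
#' @param text Sequence string, e.g. `"Biotinyl-PEG2-HSTKCitGHAKSRPVCitG"`.
#' @param c_terminal C-terminal chemistry, `"amide"` or `"free_acid"`.
#'   Defaults to `"amide"` when the biotinyl cap is present (the epitope set
#'   is synthesised as a C-terminal carboxamide) and `"free_acid"` otherwise.
#' @param protein_offset Optional integer added to the peptide index to give
#'   parent-protein numbering (616 maps His1 to His617 of the fibrin
#'   alpha chain). `NA` leaves `protein_index` unset.
#' @return A tibble of class `modified_peptide` with columns `index`,
#'   `one_letter` (parent residue), `ptm` (`none`, `Cit`, `hCit`, `KAc`),
#'   `residue` (display code) and `protein_index`, plus attributes
#'   `n_cap` (`"free"` or `"biotinyl_PEG2"`) and `c_cap`.
#' @export
#' @examples
#' p <- parse_peptide("Biotinyl-PEG2-HSTKRGHAKSRPVRG")
#' peptide_mass(p)
parse_peptide <- function(text, c_terminal = NULL, protein_offset = NA_integer_) {
  stopifnot(is.character(text), length(text) == 1)
  if (!nzchar(text)) {
    abort("empty peptide sequence")
  }
  has_cap <- grepl(BIOTIN_PREFIX_RE, text)
  body <- sub(BIOTIN_PREFIX_RE, "", text)
  if (!nzchar(body)) {
    abort("peptide sequence contains only a cap prefix")
  }

  one_letter <- character()
  ptm <- character()
  i <- 1L
  nb <- nchar(body)
  while (i <= nb) {
    rest <- substr(body, i, nb)
    if (startsWith(rest, "hCit")) {
      one_letter <- c(one_letter, "K"); ptm <- c(ptm, "hCit"); i <- i + 4L
    } else if (startsWith(rest, "K(Ac)")) {
      one_letter <- c(one_letter, "K"); ptm <- c(ptm, "KAc"); i <- i + 5L
    } else if (startsWith(rest, "Cit")) {
      one_letter <- c(one_letter, "R"); ptm <- c(ptm, "Cit"); i <- i + 3L
    } else {
      ch <- substr(body, i, i)
      if (!ch %in% names(AA_AVERAGE_MASS)) {
        abort(sprintf("unknown token at position %d of '%s': '%s'", i, body, ch))
      }
      one_letter <- c(one_letter, ch); ptm <- c(ptm, "none"); i <- i + 1L
    }
  }

  if (is.null(c_terminal)) {
    c_terminal <- if (has_cap) "amide" else "free_acid"
  }
  c_terminal <- match.arg(c_terminal, c("amide", "free_acid"))

  out <- tibble(
    index = seq_along(one_letter),
    one_letter = one_letter,
    ptm = ptm,
    residue = dplyr::case_when(
      ptm == "Cit" ~ "Cit",
      ptm == "hCit" ~ "hCit",
      ptm == "KAc" ~ "K(Ac)",
      TRUE ~ one_letter
    ),
    protein_index = if (is.na(protein_offset)) NA_integer_ else seq_along(one_letter) + as.integer(protein_offset)
  )
  structure(out,
    class = c("modified_peptide", class(out)),
    n_cap = if (has_cap) "biotinyl_PEG2" else "free",
    c_cap = c_terminal
  )
}

#' Format a parsed peptide back to its canonical sequence string
#'
#' Round-trips with [parse_peptide()]: `format_peptide(parse_peptide(x)) == x`
#' for canonical input (prefix spelled `Biotinyl-PEG2-`).
#'
#' @param p A `modified_peptide`.
#' @return A single string.
#' @export
format_peptide <- function(p) {
  stopifnot(inherits(p, "modified_peptide"))
  prefix <- if (identical(attr(p, "n_cap"), "biotinyl_PEG2")) "Biotinyl-PEG2-" else ""
  paste0(prefix, paste(p$residue, collapse = ""))
}

#' Validate PTM placement against a declared parent sequence
#'
#' Chemically every Cit sits on an Arg position and every hCit/K(Ac) on a
#' Lys position by construction of the grammar; this check additionally
#' flags positions where the parsed parent residue disagrees with a declared
#' unmodified template (e.g. a Cit token at a position that is not R in the
#' template).
#'
#' @param p A `modified_peptide`.
#' @param parent Unmodified one-letter template string of the same length.
#' @return A tibble of mismatching positions (zero rows when consistent).
#' @export
validate_ptm_sites <- function(p, parent) {
  stopifnot(inherits(p, "modified_peptide"))
  parent_chars <- strsplit(parent, "")[[1]]
  if (length(parent_chars) != nrow(p)) {
    abort("parent template length does not match peptide length")
  }
  tibble(
    index = p$index, residue = p$residue, ptm = p$ptm,
    parent = parent_chars
  ) %>%
    filter(.data$parent != p$one_letter)
}

#' Average molecular mass of a modified peptide
#'
#' Sums residue average masses, adds one water for the intact chain, then
#' applies PTM deltas and terminal-cap contributions.
#'
#' @param p A `modified_peptide`.
#' @param masses Mass configuration, see [ptm_mass_defaults()].
#' @return Mass in Da (full precision; calculated ESI-MS tables print 0.1 Da).
#' @export
#' @examples
#' peptide_mass(parse_peptide("G"))  # glycine free acid, 75.07 Da
peptide_mass <- function(p, masses = ptm_mass_defaults()) {
  stopifnot(inherits(p, "modified_peptide"))
  unknown <- setdiff(p$one_letter, names(masses$residues))
  if (length(unknown)) {
    abort(sprintf("unsupported residue(s): %s", paste(unknown, collapse = ", ")))
  }
  unknown_ptm <- setdiff(p$ptm, names(masses$ptm))
  if (length(unknown_ptm)) {
    abort(sprintf("unsupported PTM(s): %s", paste(unknown_ptm, collapse = ", ")))
  }
  m <- sum(masses$residues[p$one_letter]) + sum(masses$ptm[p$ptm]) + masses$water
  if (identical(attr(p, "c_cap"), "amide")) m <- m + masses$amide_cap_delta
  if (identical(attr(p, "n_cap"), "biotinyl_PEG2")) m <- m + masses$biotinyl_peg2_acyl
  unname(m)
}

#' Integer formal charge of a modified peptide
#'
#' Counting model: each ionisable group contributes a full integer charge
#' when the pH is on the charged side of its (crude) pKa, zero otherwise.
#' At pH 7 this gives Arg +1, Lys +1, His 0, Asp/Glu -1; Cit, hCit and
#' K(Ac) are neutral (the modification removes the basic group). An acylated
#' N terminus and an amidated C terminus are uncharged; free termini
#' contribute +1 / -1 at neutral pH and cancel.
#'
#' @param p A `modified_peptide`.
#' @param ph pH in `[0, 14]`.
#' @param pka Named vector of group pKa thresholds.
#' @return Signed integer charge.
#' @export
#' @examples
#' peptide_charge(parse_peptide("Biotinyl-PEG2-HSTKRGHAKSRPVRG"))  # +5
peptide_charge <- function(p, ph = 7,
                           pka = c(R = 12.5, K = 10.5, H = 6.0, D = 3.9,
                                   E = 4.1, nterm = 9.0, cterm = 3.1)) {
  stopifnot(inherits(p, "modified_peptide"), ph >= 0, ph <= 14)
  side <- 0L
  for (i in seq_len(nrow(p))) {
    if (p$ptm[i] != "none") next  # modified side chains are neutral
    aa <- p$one_letter[i]
    if (aa %in% c("R", "K", "H") && ph < pka[[aa]]) side <- side + 1L
    if (aa %in% c("D", "E") && ph > pka[[aa]]) side <- side - 1L
  }
  nterm <- if (identical(attr(p, "n_cap"), "free") && ph < pka[["nterm"]]) 1L else 0L
  cterm <- if (identical(attr(p, "c_cap"), "free_acid") && ph > pka[["cterm"]]) -1L else 0L
  side + nterm + cterm
}

#' @export
print.modified_peptide <- function(x, ...) {
  cat(sprintf(
    "<modified_peptide> %d residues, N-cap %s, C-term %s\n  %s\n",
    nrow(x), attr(x, "n_cap"), attr(x, "c_cap"), format_peptide(x)
  ))
  invisible(x)
}
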