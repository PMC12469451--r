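# Circular dichroism: mean residue ellipticity and Chen-style helix
# fraction from the 222 nm band.

#' Mean residue ellipticity from a measured CD spectrum
#'
#' Converts measured ellipticity (millidegrees) to mean residue ellipticity
#' MRE = theta * Mr / (10 * c * l * n) in deg cm^2 dmol^-1, where `c` is the
#' concentration in mg/mL, `l` the pathlength in cm and `n` the number of
#' peptide bonds. The factor 10 belongs to this unit choice; conventions in
#' the literature differ by powers of ten, so the full factor chain is fixed
#' here and tested.
#'
#' @param data Data frame with columns `wavelength` (nm, strictly
#'   increasing) and `ellipticity` (measured theta, mdeg).
#' @param mr Peptide molecular mass, Da (e.g. from [peptide_mass()]).
#' @param concentration Peptide concentration in mg/mL (> 0).
#' @param pathlength Cuvette pathlength in cm (> 0).
#' @param n_bonds Number of peptide bonds. For an n-residue chain this is
#'   n - 1, plus one per acylated/amidated terminus; see
#'   [peptide_bond_count()].
#' @return The input tibble with an added `mre` column (deg cm^2 dmol^-1).
#' @export
#' @examples
#' spec <- tibble::tibble(wavelength = c(200, 222), ellipticity = c(-30, -20))
#' mean_residue_ellipticity(spec, mr = 2216.6, concentration = 0.5,
#'                          pathlength = 0.1, n_bonds = 14)
mean_residue_ellipticity <- function(data, mr, concentration, pathlength, n_bonds) {
  stopifnot(all(c("wavelength", "ellipticity") %in% names(data)))
  if (concentration <= 0) abort("concentration must be > 0")
  if (pathlength <= 0) abort("pathlength must be > 0")
  if (n_bonds < 1) abort("n_bonds must be >= 1")
  if (is.unsorted(data$wavelength, strictly = TRUE)) {
    abort("wavelengths must be strictly increasing")
  }
  as_tibble(data) %>%
    mutate(mre = .data$ellipticity * mr / (10 * concentration * pathlength * n_bonds))
}

#' Number of peptide bonds for MRE normalisation
#'
#' length - 1 backbone bonds, plus one for an N-terminal acyl cap and one
#' for a C-terminal amide, both of which add an amide bond to the chain.
#'
#' @param p A `modified_peptide`.
#' @return Integer bond count.
#' @export
peptide_bond_count <- function(p) {
  stopifnot(inherits(p, "modified_peptide"))
  n <- nrow(p) - 1L
  if (identical(attr(p, "n_cap"), "biotinyl_PEG2")) n <- n + 1L
  if (identical(attr(p, "c_cap"), "amide")) n <- n + 1L
  n
}

#' Alpha-helix fraction from MRE at 222 nm
#'
#' Chen-style chain-length-corrected estimate:
#' f = MRE222 / (theta_inf * (1 - k / n_residues)), clamped to `[0, 1]`.
#' theta_inf is the limiting 222 nm ellipticity of an infinite helix and k
#' the chain-length correction; both are overridable.
#'
#' @param mre222 Mean residue ellipticity at 222 nm, deg cm^2 dmol^-1.
#' @param n_residues Number of residues (>= 3).
#' @param theta_inf Infinite-helix MRE at 222 nm (default -39500).
#' @param k Chain-length correction (default 2.57).
#' @return Helix fraction in `[0, 1]` (vectorised over `mre222`).
#' @export
#' @examples
#' helix_fraction(-6000, 15)
helix_fraction <- function(mre222, n_residues, theta_inf = -39500, k = 2.57) {
  stopifnot(n_residues >= 3)
  f <- mre222 / (theta_inf * (1 - k / n_residues))
  pmin(1, pmax(0, f))
}

#' Estimate helix content from a spectrum in one call
#'
#' Computes MRE, linearly interpolates at 222 nm, and applies
#' [helix_fraction()].
#'
#' @inheritParams mean_residue_ellipticity
#' @param p A `modified_peptide` supplying mass, bond count and length.
#' @param ... Passed to [helix_fraction()].
#' @return One-row tibble with `mre222` and `helix_fraction`.
#' @export
cd_helix_content <- function(data, p, concentration, pathlength, ...) {
  m <- mean_residue_ellipticity(data, peptide_mass(p), concentration,
                                pathlength, peptide_bond_count(p))
  if (min(m$wavelength) > 222 || max(m$wavelength) < 222) {
    abort("spectrum does not cover 222 nm")
  }
  mre222 <- stats::approx(m$wavelength, m$mre, xout = 222)$y
  tibble(mre222 = mre222,
         helix_fraction = helix_fraction(mre222, nrow(p), ...))
}

#' Read a two-column CD spectrum file
#'
#' Tab- or whitespace-separated `wavelength` (nm), `ellipticity` (mdeg),
#' with or without a header line.
#'
#' @param path File path.
#' @return Tibble with `wavelength`, `ellipticity`.
#' @export
read_cd_spectrum <- function(path) {
  first <- readLines(path, n = 1)
  has_header <- grepl("[A-Za-z]", first)
  df <- readr::read_table(path, col_names = has_header, show_col_types = FALSE)
  names(df)[1:2] <- c("wavelength", "ellipticity")
  as_tibble(df[, 1:2])
}

#' Plot an MRE curve
#'
#' @param data Tibble from [mean_residue_ellipticity()].
#' @return A ggplot.
#' @export
plot_mre <- function(data) {
  ggplot2::ggplot(data, ggplot2::aes(.data$wavelength, .data$mre)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "wavelength (nm)",
                  y = expression(theta[MRE] ~ (deg ~ cm^2 ~ dmol^-1)))
}
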