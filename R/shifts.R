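# Conformational chemical-shift deviations (delta-delta) relative to
# random-coil references, with PTM-aware reference lookup, and the
# secondary-structure tendency they imply.

#' Random-coil chemical-shift reference table
#'
#' Ships Wishart-style peptide random-coil Halpha and Calpha shifts for the
#' 20 canonical residues plus citrulline, homocitrulline and acetyl-lysine.
#' The PTM rows are parent-residue values with small corrections and are
#' deliberately stored in an editable TSV
#' (`system.file("extdata", "random_coil_shifts.tsv", package = "ptmensemble")`)
#' so measured values can be swapped in without touching code.
#'
#' @param path Optional alternative TSV with columns
#'   `residue`, `nucleus` (`HA`/`CA`), `shift` (ppm).
#' @return Tibble with columns `residue`, `nucleus`, `shift`.
#' @export
random_coil_shifts <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "random_coil_shifts.tsv", package = "ptmensemble")
  }
  readr::read_tsv(path, comment = "#", show_col_types = FALSE)
}

residue_type_code <- function(p) {
  ifelse(p$ptm == "none", p$one_letter, p$ptm)
}

#' Per-residue conformational shift map
#'
#' Delta-delta = observed shift minus random-coil reference, per residue and
#' nucleus. The reference is looked up by residue type *including* the PTM,
#' so modified residues are compared against their own corrected
#' random-coil values, not the parent residue's. Positive values are
#' downfield of random coil.
#'
#' @param observed Data frame with columns `residue_index`, `nucleus`
#'   (`"HA"` or `"CA"`), `shift` (ppm).
#' @param p The `modified_peptide` the shifts belong to.
#' @param reference Random-coil table, see [random_coil_shifts()].
#' @return Tibble with `residue_index`, `residue_type`, `nucleus`,
#'   `observed`, `random_coil`, `delta` (ppm).
#' @export
conformational_shift <- function(observed, p, reference = random_coil_shifts()) {
  stopifnot(all(c("residue_index", "nucleus", "shift") %in% names(observed)),
            inherits(p, "modified_peptide"))
  if (anyDuplicated(observed[c("residue_index", "nucleus")])) {
    abort("observed table has duplicate (residue_index, nucleus) entries")
  }
  types <- tibble(residue_index = p$index, residue_type = residue_type_code(p))
  out <- as_tibble(observed) %>%
    rename(observed = "shift") %>%
    left_join(types, by = "residue_index") %>%
    left_join(rename(reference, random_coil = "shift"),
              by = c("residue_type" = "residue", "nucleus"))
  missing <- filter(out, is.na(.data$random_coil))
  if (nrow(missing)) {
    abort(sprintf(
      "no random-coil reference for: %s",
      paste(unique(paste0(missing$residue_type, "/", missing$nucleus)), collapse = ", ")
    ))
  }
  out %>%
    mutate(delta = .data$observed - .data$random_coil) %>%
    select("residue_index", "residue_type", "nucleus",
           "observed", "random_coil", "delta")
}

#' Classify the secondary-structure tendency of a shift-deviation map
#'
#' Slides a window over the per-residue map and labels each window from the
#' joint sign pattern of the mean Halpha and Calpha deviations:
#' helix-like when mean dHA < -tau_h and mean dCA > +tau_c. The reversed
#' sign pattern (dHA downfield, dCA upfield) is shared by extended strands
#' and turns, so it is split by magnitude: extended-like when the pattern is
#' strong (beyond twice each threshold, the full-strand regime),
#' turn-compatible when it holds at the base thresholds only; otherwise
#' coil. The thresholds are the smallest deviation treated as meaningful
#' and are deliberately config-exposed.
#'
#' @param deltas Output of [conformational_shift()] (needs `residue_index`,
#'   `nucleus`, `delta`).
#' @param window Window length in residues (>= 3).
#' @param tau_h Halpha threshold, ppm (default 0.1).
#' @param tau_c Calpha threshold, ppm (default 0.5).
#' @return Tibble with `window_start`, `window_end`, `mean_dha`, `mean_dca`,
#'   `tendency`.
#' @export
classify_tendency <- function(deltas, window = 3, tau_h = 0.1, tau_c = 0.5) {
  if (window < 3) abort("window must be >= 3")
  wide <- deltas %>%
    select("residue_index", "nucleus", "delta") %>%
    tidyr::pivot_wider(names_from = "nucleus", values_from = "delta") %>%
    arrange(.data$residue_index)
  n <- nrow(wide)
  if (window > n) abort("window longer than the peptide")
  ha <- if ("HA" %in% names(wide)) wide$HA else rep(NA_real_, n)
  ca <- if ("CA" %in% names(wide)) wide$CA else rep(NA_real_, n)
  starts <- seq_len(n - window + 1)
  purrr::map_dfr(starts, function(s) {
    idx <- s:(s + window - 1)
    mh <- mean(ha[idx], na.rm = TRUE)
    mc <- mean(ca[idx], na.rm = TRUE)
    lab <- if (is.na(mh) || is.na(mc)) {
      "coil"
    } else if (mh < -tau_h && mc > tau_c) {
      "helix-like"
    } else if (mh > 2 * tau_h && mc < -2 * tau_c) {
      "extended-like"
    } else if (mh > tau_h && mc < -tau_c) {
      "turn-compatible"
    } else {
      "coil"
    }
    tibble(window_start = wide$residue_index[s],
           window_end = wide$residue_index[s + window - 1],
           mean_dha = mh, mean_dca = mc, tendency = lab)
  })
}

#' Compare predicted and observed chemical shifts
#'
#' Per-nucleus RMSD and bias over the overlap of two shift tables; used to
#' judge how well ensemble-back-calculated shifts reproduce the experiment.
#' Modified residues may be absent from predictions (predictors typically
#' cover canonical residues only); they simply drop out of the overlap.
#'
#' @param predicted,observed Data frames with `residue_index`, `nucleus`,
#'   `shift`.
#' @return Tibble with `nucleus`, `n`, `bias` (mean observed - predicted,
#'   ppm) and `rmsd` (ppm).
#' @export
compare_shifts <- function(predicted, observed) {
  joined <- dplyr::inner_join(
    rename(as_tibble(predicted), predicted = "shift"),
    rename(as_tibble(observed), observed = "shift"),
    by = c("residue_index", "nucleus")
  )
  if (!nrow(joined)) abort("no overlapping (residue, nucleus) entries")
  joined %>%
    group_by(.data$nucleus) %>%
    summarise(
      n = dplyr::n(),
      bias = mean(.data$observed - .data$predicted),
      rmsd = sqrt(mean((.data$observed - .data$predicted)^2)),
      .groups = "drop"
    )
}

#' Read a TSV shift table
#'
#' Columns: `residue_index`, `residue_type`, `nucleus`, `shift` (ppm);
#' `residue_type` is optional.
#'
#' @param path File path.
#' @return Tibble.
#' @export
read_shift_table <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE)
}

#' Plot a conformational shift map
#'
#' Bar map of delta-delta per residue, faceted by nucleus, with the usual
#' sign convention (negative Halpha together with positive Calpha hints at
#' helix; the reverse at extended structure).
#'
#' @param deltas Output of [conformational_shift()].
#' @return A ggplot.
#' @export
plot_shift_map <- function(deltas) {
  ggplot2::ggplot(deltas, ggplot2::aes(.data$residue_index, .data$delta)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_col(width = 0.7, fill = "steelblue") +
    ggplot2::facet_wrap(~nucleus, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "residue", y = expression(Delta * delta ~ (ppm)))
}
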