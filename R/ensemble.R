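# Conformational-ensemble container and per-frame / per-residue
# observables: equilibration discard, radius of gyration, dihedral-based
# secondary structure, populations with block-averaged errors, contacts.

#' Construct a conformational ensemble
#'
#' Frames x atoms x 3 coordinates (nm) plus an atom table and per-frame
#' provenance. This is the container every trajectory observable and the
#' clustering pipeline operate on.
#'
#' @param coords Numeric array `[n_frames, n_atoms, 3]`, nm, finite.
#' @param topology Data frame with one row per atom: `atom` (name),
#'   `residue` (1-based index), `residue_code` (one-letter or PTM code),
#'   `mass` (Da), `element`.
#' @param trajectory_label Per-frame source id (recycled if length 1).
#' @param time_per_frame Time spacing between frames, ns.
#' @return Object of class `conformation_ensemble`.
#' @export
conformation_ensemble <- function(coords, topology, trajectory_label = "traj1",
                                  time_per_frame = 1) {
  stopifnot(length(dim(coords)) == 3, dim(coords)[3] == 3)
  if (dim(coords)[1] < 1) abort("ensemble must have at least one frame")
  if (!all(is.finite(coords))) abort("coordinates must be finite")
  stopifnot(nrow(topology) == dim(coords)[2],
            all(c("atom", "residue", "mass") %in% names(topology)))
  trajectory_label <- rep_len(as.character(trajectory_label), dim(coords)[1])
  structure(
    list(coords = coords, topology = as_tibble(topology),
         trajectory_label = trajectory_label,
         time_per_frame = time_per_frame),
    class = "conformation_ensemble"
  )
}

#' Number of frames in an ensemble
#' @param ens A `conformation_ensemble`.
#' @return Integer.
#' @export
n_frames <- function(ens) dim(ens$coords)[1]

#' @export
print.conformation_ensemble <- function(x, ...) {
  cat(sprintf(
    "<conformation_ensemble> %d frames x %d atoms (%d residues), %s ns/frame, trajectories: %s\n",
    n_frames(x), nrow(x$topology), max(x$topology$residue),
    format(x$time_per_frame),
    paste(unique(x$trajectory_label), collapse = ", ")
  ))
  invisible(x)
}

subset_frames <- function(ens, keep) {
  conformation_ensemble(ens$coords[keep, , , drop = FALSE], ens$topology,
                        ens$trajectory_label[keep], ens$time_per_frame)
}

#' Pool several ensembles sharing a topology
#'
#' @param ... `conformation_ensemble` objects with identical topologies.
#' @return A pooled `conformation_ensemble` (trajectory labels preserved).
#' @export
bind_ensembles <- function(...) {
  lst <- list(...)
  if (length(lst) == 1 && is.list(lst[[1]]) && !inherits(lst[[1]], "conformation_ensemble")) {
    lst <- lst[[1]]
  }
  stopifnot(length(lst) >= 1)
  coords <- do.call(abind_frames, lapply(lst, function(e) e$coords))
  conformation_ensemble(coords, lst[[1]]$topology,
                        unlist(lapply(lst, function(e) e$trajectory_label)),
                        lst[[1]]$time_per_frame)
}

abind_frames <- function(...) {
  mats <- list(...)
  n <- sum(vapply(mats, function(m) dim(m)[1], integer(1)))
  out <- array(0, c(n, dim(mats[[1]])[2], 3))
  at <- 1
  for (m in mats) {
    out[at:(at + dim(m)[1] - 1), , ] <- m
    at <- at + dim(m)[1]
  }
  out
}

#' Discard the equilibration phase of an ensemble
#'
#' Drops the leading frames, by fraction of the trajectory or by
#' simulation time. The default 20% mirrors discarding the first 40 ns of
#' a 200 ns trajectory. Applied per trajectory label, so pooled ensembles
#' lose the head of each source trajectory.
#'
#' @param ens A `conformation_ensemble`.
#' @param fraction Fraction of frames to drop (in `[0, 1)`).
#' @param ns Alternative: time to drop, ns (overrides `fraction`).
#' @return The trimmed ensemble.
#' @export
#' @examples
#' # a 200-frame, 1 ns/frame ensemble keeps 160 frames by default
discard_equilibration <- function(ens, fraction = 0.2, ns = NULL) {
  stopifnot(inherits(ens, "conformation_ensemble"))
  keep <- logical(n_frames(ens))
  for (lab in unique(ens$trajectory_label)) {
    idx <- which(ens$trajectory_label == lab)
    n_drop <- if (!is.null(ns)) {
      round(ns / ens$time_per_frame)
    } else {
      floor(fraction * length(idx))
    }
    if (n_drop >= length(idx)) {
      abort("equilibration discard would remove every frame")
    }
    keep[idx[seq_len(length(idx) - n_drop) + n_drop]] <- TRUE
  }
  subset_frames(ens, keep)
}

#' Per-frame radius of gyration
#'
#' Mass-weighted RMS distance of all atoms from the frame's centre of
#' mass: Rg = sqrt(sum m_i |x_i - xbar|^2 / sum m_i).
#'
#' @param ens A `conformation_ensemble`.
#' @return Tibble with `frame`, `trajectory`, `rg` (nm).
#' @export
radius_of_gyration <- function(ens) {
  stopifnot(inherits(ens, "conformation_ensemble"))
  m <- ens$topology$mass
  w <- m / sum(m)
  nf <- n_frames(ens)
  rg <- vapply(seq_len(nf), function(f) {
    x <- ens$coords[f, , ]
    com <- colSums(x * w)
    sqrt(sum(w * rowSums((x - matrix(com, nrow(x), 3, byrow = TRUE))^2)))
  }, numeric(1))
  tibble(frame = seq_len(nf), trajectory = ens$trajectory_label, rg = rg)
}

#' Summarise per-frame Rg as mean and standard deviation
#'
#' @param rg_table Output of [radius_of_gyration()].
#' @return Tibble with `trajectory`, `mean_rg`, `sd_rg`, `n`.
#' @export
rg_summary <- function(rg_table) {
  rg_table %>%
    group_by(.data$trajectory) %>%
    summarise(mean_rg = mean(.data$rg), sd_rg = sd(.data$rg), n = dplyr::n(),
              .groups = "drop")
}

#' Backbone dihedral angles per frame and residue
#'
#' phi_i from C(i-1)-N(i)-CA(i)-C(i), psi_i from N(i)-CA(i)-C(i)-N(i+1);
#' terminal residues get NA for the undefined angle.
#'
#' @param ens A `conformation_ensemble` with N, CA, C backbone atoms.
#' @return Tibble with `frame`, `residue`, `phi`, `psi` (degrees).
#' @export
dihedral_angles <- function(ens) {
  topo <- ens$topology
  nres <- max(topo$residue)
  at <- function(res, name) {
    i <- which(topo$residue == res & topo$atom == name)
    if (length(i) != 1) abort(sprintf("backbone atom %s missing in residue %d", name, res))
    ens$coords[, i, , drop = TRUE]
  }
  as_mat <- function(x) if (is.null(dim(x))) matrix(x, nrow = 1) else x
  nf <- n_frames(ens)
  N <- lapply(1:nres, at, name = "N")
  CA <- lapply(1:nres, at, name = "CA")
  C <- lapply(1:nres, at, name = "C")
  purrr::map_dfr(1:nres, function(i) {
    phi <- if (i == 1) rep(NA_real_, nf) else {
      row_dihedral(as_mat(C[[i - 1]]), as_mat(N[[i]]), as_mat(CA[[i]]), as_mat(C[[i]]))
    }
    psi <- if (i == nres) rep(NA_real_, nf) else {
      row_dihedral(as_mat(N[[i]]), as_mat(CA[[i]]), as_mat(C[[i]]), as_mat(N[[i + 1]]))
    }
    tibble(frame = seq_len(nf), residue = i, phi = phi, psi = psi)
  }) %>% arrange(.data$frame, .data$residue)
}

#' Default Ramachandran windows for secondary-structure assignment
#'
#' H when phi in (-100, -30) and psi in (-80, -5); E when phi in
#' (-180, -90) and psi in (90, 180) or (-180, -170); else C. A transparent
#' dihedral rule rather than a pattern-recognition algorithm, so every
#' assignment is checkable by hand; a DSSP-style assigner can be slotted in
#' through the `windows` argument seam.
#'
#' @return List of window definitions.
#' @export
ss_windows_defaults <- function() {
  list(
    H = function(phi, psi) phi > -100 & phi < -30 & psi > -80 & psi < -5,
    E = function(phi, psi) phi > -180 & phi < -90 &
      ((psi > 90 & psi < 180) | (psi > -180 & psi < -170))
  )
}

#' Assign per-residue secondary structure from backbone dihedrals
#'
#' Ramachandran-window assignment with a minimum-run rule: H or E labels
#' must occur in runs of at least `min_run` consecutive residues, shorter
#' runs revert to C (an isolated helical dihedral pair is not a helix).
#' Terminal residues, lacking one dihedral, are labelled C.
#'
#' @param ens A `conformation_ensemble`.
#' @param windows See [ss_windows_defaults()].
#' @param min_run Minimum run length for H/E (default 3).
#' @return Tibble with `frame`, `residue`, `ss` (`"H"`, `"E"`, `"C"`).
#' @export
assign_secondary_structure <- function(ens, windows = ss_windows_defaults(),
                                       min_run = 3) {
  dh <- dihedral_angles(ens)
  lab <- rep("C", nrow(dh))
  ok <- !is.na(dh$phi) & !is.na(dh$psi)
  lab[ok & windows$E(dh$phi, dh$psi)] <- "E"
  lab[ok & windows$H(dh$phi, dh$psi)] <- "H"
  dh$ss <- lab
  nres <- max(dh$residue)
  dh %>%
    arrange(.data$frame, .data$residue) %>%
    group_by(.data$frame) %>%
    mutate(ss = enforce_min_run(.data$ss, min_run)) %>%
    ungroup() %>%
    select("frame", "residue", "ss")
}

enforce_min_run <- function(ss, min_run) {
  r <- rle(ss)
  r$values[r$values != "C" & r$lengths < min_run] <- "C"
  inverse.rle(r)
}

#' Per-residue secondary-structure populations with block-averaged errors
#'
#' Fraction of frames per residue in H, E and C, with the standard error
#' of the mean estimated by block averaging (frames split into contiguous
#' blocks, SEM = sd of block means / sqrt(n_blocks)); frames from MD are
#' autocorrelated, so the naive SEM would be optimistic.
#'
#' @param ens A `conformation_ensemble` (>= 2 frames).
#' @param n_blocks Number of blocks (default 5).
#' @return Tibble with `residue`, `ss`, `fraction`, `sem`; fractions sum to
#'   1 per residue.
#' @export
ss_population <- function(ens, n_blocks = 5) {
  if (n_frames(ens) < 2) abort("need at least 2 frames")
  ssdf <- assign_secondary_structure(ens)
  nf <- n_frames(ens)
  block <- pmin(ceiling(seq_len(nf) / (nf / n_blocks)), n_blocks)
  ssdf$block <- block[ssdf$frame]
  labels <- c("H", "E", "C")
  per_block <- ssdf %>%
    group_by(.data$residue, .data$block) %>%
    summarise(total = dplyr::n(),
              H = sum(.data$ss == "H") / .data$total[1],
              E = sum(.data$ss == "E") / .data$total[1],
              C = sum(.data$ss == "C") / .data$total[1],
              .groups = "drop") %>%
    tidyr::pivot_longer(dplyr::all_of(labels), names_to = "ss",
                        values_to = "fraction")
  overall <- ssdf %>%
    group_by(.data$residue) %>%
    summarise(total = dplyr::n(),
              H = sum(.data$ss == "H") / .data$total[1],
              E = sum(.data$ss == "E") / .data$total[1],
              C = sum(.data$ss == "C") / .data$total[1],
              .groups = "drop") %>%
    tidyr::pivot_longer(dplyr::all_of(labels), names_to = "ss",
                        values_to = "fraction")
  sems <- per_block %>%
    group_by(.data$residue, .data$ss) %>%
    summarise(sem = sd(.data$fraction) / sqrt(dplyr::n()), .groups = "drop")
  overall %>%
    select("residue", "ss", "fraction") %>%
    left_join(sems, by = c("residue", "ss")) %>%
    mutate(ss = factor(.data$ss, levels = labels)) %>%
    arrange(.data$residue, .data$ss)
}

#' Residue-residue contact frequencies over an ensemble
#'
#' A residue pair is in contact in a frame when the minimum distance over
#' their heavy atoms is below `cutoff`. Frequencies are symmetric; the
#' diagonal band `|i - j| < min_separation` is masked (NA).
#'
#' @param ens A `conformation_ensemble`.
#' @param cutoff Contact cutoff, nm (default 0.5).
#' @param min_separation Minimum residue separation reported (default 2).
#' @return Tibble with `res_i`, `res_j` (i < j), `frequency` in `[0, 1]`.
#' @export
contact_map <- function(ens, cutoff = 0.5, min_separation = 2) {
  if (cutoff <= 0) abort("cutoff must be > 0")
  topo <- ens$topology
  heavy <- which(topo$element != "H")
  nres <- max(topo$residue)
  nf <- n_frames(ens)
  by_res <- split(heavy, topo$residue[heavy])
  pairs <- expand.grid(res_i = 1:nres, res_j = 1:nres) %>%
    filter(.data$res_j - .data$res_i >= min_separation)
  freq <- purrr::map_dbl(seq_len(nrow(pairs)), function(k) {
    ai <- by_res[[as.character(pairs$res_i[k])]]
    aj <- by_res[[as.character(pairs$res_j[k])]]
    mind <- rep(Inf, nf)
    for (a in ai) for (b in aj) {
      d <- sqrt(rowSums((matrix(ens$coords[, a, ], nf, 3) -
                           matrix(ens$coords[, b, ], nf, 3))^2))
      mind <- pmin(mind, d)
    }
    mean(mind < cutoff)
  })
  as_tibble(pairs) %>% mutate(frequency = freq)
}

#' Helical-contact prevalence summary
#'
#' Mean contact frequency at sequence offsets `|i - j|` of 3 and 4 — the
#' contacts characteristic of helical turns — plus all offsets for
#' context.
#'
#' @param contacts Output of [contact_map()].
#' @return Tibble with `offset`, `mean_frequency`, `n_pairs`.
#' @export
contact_prevalence <- function(contacts) {
  contacts %>%
    mutate(offset = .data$res_j - .data$res_i) %>%
    group_by(.data$offset) %>%
    summarise(mean_frequency = mean(.data$frequency), n_pairs = dplyr::n(),
              .groups = "drop")
}

#' Plot per-residue secondary-structure populations
#'
#' Line-and-ribbon plot per label; the ribbon is +/- one block-averaged
#' SEM.
#'
#' @param pop Output of [ss_population()].
#' @return A ggplot.
#' @export
plot_ss_population <- function(pop) {
  ggplot2::ggplot(pop, ggplot2::aes(.data$residue, .data$fraction,
                                    colour = .data$ss, fill = .data$ss)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = pmax(0, .data$fraction - .data$sem),
                                      ymax = pmin(1, .data$fraction + .data$sem)),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "residue", y = "population", colour = NULL, fill = NULL)
}

#' Plot a residue-residue contact-frequency map
#'
#' @param contacts Output of [contact_map()].
#' @return A ggplot.
#' @export
plot_contact_map <- function(contacts) {
  both <- bind_rows(contacts,
                    rename(contacts, res_i = "res_j", res_j = "res_i"))
  ggplot2::ggplot(both, ggplot2::aes(.data$res_i, .data$res_j,
                                     fill = .data$frequency)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "residue i", y = "residue j", fill = "contact\nfrequency")
}
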