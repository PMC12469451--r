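# Synthetic conformational ensembles with known ground truth: phi/psi
# Ramachandran-basin mixtures built into Cartesian chains with ideal
# peptide geometry, forward-simulated NOE volume tables, and planted
# multi-state trajectory pools. The generators test the analysis code;
# they make no claim to force-field physics.

# Ideal backbone geometry (nm / degrees), trans peptide bond.
GEOM <- list(
  b_n_ca = 0.1458, b_ca_c = 0.1525, b_c_n = 0.1329, b_c_o = 0.1230,
  b_n_h = 0.1000, b_ca_ha = 0.1090, b_ca_cb = 0.1532, b_cb_hb = 0.1090,
  a_n_ca_c = 111.0, a_ca_c_n = 116.2, a_c_n_ca = 121.7,
  a_ca_c_o = 120.5, a_c_n_h = 119.0, omega = 180.0
)

#' Default Ramachandran basin centres for the generator
#'
#' helix (-60, -45), polyproline II (-75, 145), extended (-135, 135)
#' degrees. Helix falls inside the H assignment window and extended inside
#' the E window; PPII is assigned C, so basin-weight ground truth maps
#' directly onto secondary-structure labels.
#'
#' @return Named list of `c(phi, psi)` centres.
#' @export
basin_centers <- function() {
  list(helix = c(-60, -45), ppii = c(-75, 145), extended = c(-135, 135))
}

#' Recipe for a synthetic conformational ensemble
#'
#' @param p A `modified_peptide` (or sequence string to parse).
#' @param n_frames Number of frames (>= 1).
#' @param basin_weights Either a named numeric over
#'   `c(helix, ppii, extended)` — a whole-frame conformer mixture, each
#'   frame drawing one basin for the full chain — or an
#'   `n_residues x 3` matrix of per-residue weights (columns helix, ppii,
#'   extended) sampled independently per residue. Rows/vector must sum
#'   to 1.
#' @param jitter_sd Gaussian angular jitter around the basin centre,
#'   degrees (> 0).
#' @param compaction Optional list `list(d0 = , k = )`: harmonic
#'   end-to-end (N-terminal CA to C-terminal CA) bias towards `d0` nm with
#'   stiffness `k` (1/nm^2), applied by importance resampling of frames.
#' @param seed Integer seed; generation is a pure function of
#'   (recipe, seed).
#' @param time_per_frame ns per frame (default 1).
#' @return An `ensemble_recipe` list.
#' @export
ensemble_recipe <- function(p, n_frames, basin_weights = c(helix = 0, ppii = 0.5, extended = 0.5),
                            jitter_sd = 8, compaction = NULL, seed = 1,
                            time_per_frame = 1) {
  if (is.character(p)) p <- parse_peptide(p)
  stopifnot(inherits(p, "modified_peptide"), n_frames >= 1, jitter_sd > 0)
  if (is.matrix(basin_weights)) {
    stopifnot(nrow(basin_weights) == nrow(p), ncol(basin_weights) == 3)
    stopifnot(all(abs(rowSums(basin_weights) - 1) < 1e-8))
  } else {
    basin_weights <- basin_weights[c("helix", "ppii", "extended")]
    stopifnot(abs(sum(basin_weights) - 1) < 1e-8)
  }
  structure(list(peptide = p, n_frames = as.integer(n_frames),
                 basin_weights = basin_weights, jitter_sd = jitter_sd,
                 compaction = compaction, seed = seed,
                 time_per_frame = time_per_frame),
            class = "ensemble_recipe")
}

# Topology for the reduced representation: backbone N, H (i >= 2), CA, HA,
# C, O plus a CB pseudo side chain carrying the residue's remaining mass
# and two geminal HB protons.
build_topology <- function(p) {
  masses <- ptm_mass_defaults()
  el_mass <- c(N = 14.007, C = 12.011, O = 15.999, H = 1.008)
  backbone_mass <- el_mass[["N"]] + 2 * el_mass[["C"]] + el_mass[["O"]] +
    2 * el_mass[["H"]] # N, CA, C, O, HN, HA
  purrr::map_dfr(seq_len(nrow(p)), function(i) {
    res_mass <- masses$residues[[p$one_letter[i]]] + masses$ptm[[p$ptm[i]]]
    cb_mass <- max(el_mass[["C"]], res_mass - backbone_mass - 2 * el_mass[["H"]])
    atoms <- tibble(
      atom = c("N", "HN", "CA", "HA", "CB", "HB1", "HB2", "C", "O"),
      element = c("N", "H", "C", "H", "C", "H", "H", "C", "O"),
      mass = c(el_mass[["N"]], el_mass[["H"]], el_mass[["C"]], el_mass[["H"]],
               cb_mass, el_mass[["H"]], el_mass[["H"]], el_mass[["C"]],
               el_mass[["O"]])
    )
    if (i == 1) atoms <- filter(atoms, .data$atom != "HN")
    atoms %>% mutate(residue = i,
                     residue_code = ifelse(p$ptm[i] == "none", p$one_letter[i], p$ptm[i]))
  })
}

# Tetrahedral branch directions at CA (for CB/HA) or CB (for HB1/HB2).
branch_pair <- function(u, v) {
  # u, v: unit vectors from the centre to its two placed neighbours
  s <- row_normalize(u + v)
  pvec <- row_normalize(row_cross(u, v))
  a <- 0.5894; c <- 0.8078 # ideal tetrahedral coefficients for 111 deg u-v
  list(plus = (-a) * s + c * pvec, minus = (-a) * s - c * pvec)
}

# Build frames x atoms x 3 coordinates from per-frame, per-residue phi/psi
# (degrees). phi/psi are n_frames x n_res matrices.
chain_from_dihedrals <- function(phi, psi, topo) {
  nf <- nrow(phi); nres <- ncol(phi)
  g <- GEOM
  atom_key <- paste(topo$residue, topo$atom, sep = "/")
  coords <- array(NA_real_, c(nf, nrow(topo), 3))
  put <- function(res, atom, xyz) {
    coords[, match(paste(res, atom, sep = "/"), atom_key), ] <<- xyz
  }
  ones <- function(x, y, z) matrix(rep(c(x, y, z), each = nf), nf, 3)

  N <- vector("list", nres); CA <- vector("list", nres); C <- vector("list", nres)
  N[[1]] <- ones(0, 0, 0)
  CA[[1]] <- ones(g$b_n_ca, 0, 0)
  th <- g$a_n_ca_c * DEG
  C[[1]] <- CA[[1]] + cbind(rep(-g$b_ca_c * cos(th), nf),
                            rep(g$b_ca_c * sin(th), nf), rep(0, nf))
  for (i in 2:nres) {
    N[[i]] <- nerf_place(N[[i - 1]], CA[[i - 1]], C[[i - 1]],
                         g$b_c_n, g$a_ca_c_n, psi[, i - 1])
    CA[[i]] <- nerf_place(CA[[i - 1]], C[[i - 1]], N[[i]],
                          g$b_n_ca, g$a_c_n_ca, g$omega)
    C[[i]] <- nerf_place(C[[i - 1]], N[[i]], CA[[i]],
                         g$b_ca_c, g$a_n_ca_c, phi[, i])
  }
  for (i in 1:nres) {
    put(i, "N", N[[i]]); put(i, "CA", CA[[i]]); put(i, "C", C[[i]])
    # carbonyl O: anti to the next amide nitrogen (psi + 180)
    psi_eff <- if (i < nres) psi[, i] else psi[, i]
    put(i, "O", nerf_place(N[[i]], CA[[i]], C[[i]],
                           g$b_c_o, g$a_ca_c_o, psi_eff + 180))
    if (i >= 2) {
      # amide H trans to the carbonyl O of the preceding residue
      O_prev <- coords[, match(paste(i - 1, "O", sep = "/"), atom_key), ]
      if (is.null(dim(O_prev))) O_prev <- matrix(O_prev, nf, 3)
      put(i, "HN", nerf_place(O_prev, C[[i - 1]], N[[i]],
                              g$b_n_h, g$a_c_n_h, 180))
    }
    u <- row_normalize(N[[i]] - CA[[i]])
    v <- row_normalize(C[[i]] - CA[[i]])
    br <- branch_pair(u, v)
    CB <- CA[[i]] + g$b_ca_cb * br$plus
    put(i, "CB", CB)
    put(i, "HA", CA[[i]] + g$b_ca_ha * br$minus)
    # two geminal HB protons on CB (H-C-H ideal: 1.78 A separation)
    ucb <- row_normalize(CA[[i]] - CB)
    ref <- row_normalize(N[[i]] - CB)
    pv <- row_normalize(row_cross(ucb, ref))
    qv <- row_normalize(row_cross(pv, ucb))
    ca_ <- cos(109.5 * DEG); sa <- sin(109.5 * DEG)
    # half-opening chosen so the geminal H-H separation is exactly 0.178 nm
    # (the calibration reference distance); the H-C-H angle stays ~109.5 deg
    d60 <- asin(0.178 / (2 * g$b_cb_hb * sa))
    put(i, "HB1", CB + g$b_cb_hb * (ca_ * ucb + sa * (cos(d60) * qv + sin(d60) * pv)))
    put(i, "HB2", CB + g$b_cb_hb * (ca_ * ucb + sa * (cos(d60) * qv - sin(d60) * pv)))
  }
  coords
}

#' Build a synthetic conformational ensemble from a recipe
#'
#' Samples a Ramachandran basin per frame (or per residue), adds Gaussian
#' angular jitter, and builds Cartesian coordinates with ideal bond
#' geometry (trans peptide bonds) for a reduced topology of backbone
#' N, HN, CA, HA, C, O plus a CB pseudo side chain with two geminal HB
#' protons. Bitwise reproducible given the recipe seed. The planted basin
#' labels are attached as ground truth.
#'
#' @param recipe An [ensemble_recipe()].
#' @return A `conformation_ensemble` with attributes `basin` (per-frame
#'   label for whole-frame mixtures, or `n_frames x n_res` matrix) and
#'   `recipe`.
#' @export
build_ensemble <- function(recipe) {
  stopifnot(inherits(recipe, "ensemble_recipe"))
  p <- recipe$peptide
  nres <- nrow(p)
  nf <- recipe$n_frames
  centers <- basin_centers()
  names_b <- c("helix", "ppii", "extended")
  withr::with_seed(recipe$seed, {
    if (is.matrix(recipe$basin_weights)) {
      basin <- matrix("", nf, nres)
      for (r in seq_len(nres)) {
        basin[, r] <- sample(names_b, nf, replace = TRUE,
                             prob = recipe$basin_weights[r, ])
      }
    } else {
      frame_basin <- sample(names_b, nf, replace = TRUE,
                            prob = recipe$basin_weights)
      basin <- matrix(frame_basin, nf, nres)
    }
    phi0 <- matrix(vapply(basin, function(b) centers[[b]][1], numeric(1)), nf, nres)
    psi0 <- matrix(vapply(basin, function(b) centers[[b]][2], numeric(1)), nf, nres)
    phi <- phi0 + matrix(rnorm(nf * nres, sd = recipe$jitter_sd), nf, nres)
    psi <- psi0 + matrix(rnorm(nf * nres, sd = recipe$jitter_sd), nf, nres)
    topo <- build_topology(p)
    coords <- chain_from_dihedrals(phi, psi, topo)
    if (!is.null(recipe$compaction)) {
      ca_first <- match(paste(1, "CA", sep = "/"), paste(topo$residue, topo$atom, sep = "/"))
      ca_last <- match(paste(nres, "CA", sep = "/"), paste(topo$residue, topo$atom, sep = "/"))
      dee <- sqrt(rowSums((coords[, ca_first, , drop = TRUE] -
                             coords[, ca_last, , drop = TRUE])^2))
      w <- exp(-0.5 * recipe$compaction$k * (dee - recipe$compaction$d0)^2)
      pick <- sample.int(nf, nf, replace = TRUE, prob = w)
      coords <- coords[pick, , , drop = FALSE]
      basin <- basin[pick, , drop = FALSE]
    }
  })
  ens <- conformation_ensemble(coords, topo, trajectory_label = "traj1",
                               time_per_frame = recipe$time_per_frame)
  attr(ens, "basin") <- if (is.matrix(recipe$basin_weights)) basin else basin[, 1]
  attr(ens, "recipe") <- recipe
  ens
}

#' Forward-simulate an NOE cross-peak volume table from an ensemble
#'
#' For every pair of selected protons, the effective distance is the
#' r^-6-weighted ensemble average d_eff = <r^-6>^(-1/6) (Angstrom) and the
#' peak volume is `scale * d_eff^-6`, optionally with multiplicative
#' log-normal noise. The geminal HB1/HB2 pair of `ref_residue` is flagged
#' `is_reference` so downstream calibration is self-contained; its rigid
#' geometry pins it at the calibration reference distance. The planted
#' `d_eff` is kept on the table as ground truth (drop it to simulate a
#' blind peak list).
#'
#' @param ens A `conformation_ensemble` with protons.
#' @param scale Volume scale factor (> 0).
#' @param noise_sd Log-normal sigma for multiplicative volume noise
#'   (0 = noise-free).
#' @param protons Proton atom names eligible for peaks.
#' @param max_distance Peaks with d_eff above this (Angstrom) are dropped
#'   (unobservable), except the reference pair. Default 6 keeps some
#'   very-weak-class peaks.
#' @param ref_residue Residue carrying the geminal reference pair.
#' @param seed Seed for the noise draw.
#' @return Tibble with `res_a`, `atom_a`, `res_b`, `atom_b`, `volume`,
#'   `is_reference`, `d_eff`.
#' @export
forward_noe <- function(ens, scale = 1e6, noise_sd = 0,
                        protons = c("HA", "HN", "HB1", "HB2"),
                        max_distance = 6, ref_residue = 7, seed = 1) {
  stopifnot(inherits(ens, "conformation_ensemble"), scale > 0, noise_sd >= 0)
  topo <- ens$topology
  sel <- which(topo$atom %in% protons)
  if (length(sel) < 2) abort("no eligible proton pairs")
  nf <- n_frames(ens)
  pairs <- utils::combn(sel, 2)
  d_eff <- vapply(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1, k]; b <- pairs[2, k]
    d <- sqrt(rowSums((matrix(ens$coords[, a, ], nf, 3) -
                         matrix(ens$coords[, b, ], nf, 3))^2)) * 10 # nm -> A
    mean(d^-6)^(-1 / 6)
  }, numeric(1))
  out <- tibble(
    res_a = topo$residue[pairs[1, ]], atom_a = topo$atom[pairs[1, ]],
    res_b = topo$residue[pairs[2, ]], atom_b = topo$atom[pairs[2, ]],
    d_eff = d_eff
  ) %>%
    mutate(is_reference = .data$res_a == ref_residue & .data$res_b == ref_residue &
             .data$atom_a %in% c("HB1", "HB2") & .data$atom_b %in% c("HB1", "HB2")) %>%
    filter(.data$d_eff <= max_distance | .data$is_reference) %>%
    mutate(volume = scale * .data$d_eff^-6)
  if (noise_sd > 0) {
    withr::with_seed(seed, {
      out$volume <- out$volume * exp(rnorm(nrow(out), sd = noise_sd))
    })
  }
  select(out, "res_a", "atom_a", "res_b", "atom_b", "volume",
         "is_reference", "d_eff")
}

#' Pooled multi-trajectory ensemble with planted cluster states
#'
#' Builds `n_traj` trajectories over `k_states` conformational states
#' (distinct whole-chain basin patterns: all-helix, all-extended, all-PPII,
#' then alternating patterns) and pools them with per-frame state labels as
#' ground truth. `separation` is the ratio of between-state structural
#' difference to within-state spread: the angular jitter is `120 /
#' separation` degrees, so larger values give tighter, better separated
#' states. Per-trajectory state mixtures are configurable, e.g. a state
#' private to one trajectory.
#'
#' @param k_states Number of planted states (1-4).
#' @param frames_per_traj Frames per trajectory.
#' @param n_traj Number of trajectories.
#' @param separation Between/within spread ratio (default 8).
#' @param seed Integer seed.
#' @param state_mix Optional `n_traj x k_states` row-stochastic matrix of
#'   per-trajectory state probabilities (default uniform).
#' @param p Peptide (default: the unmodified 15-mer epitope template).
#' @return A pooled `conformation_ensemble` with attribute `state`
#'   (per-frame ground-truth state id).
#' @export
planted_cluster_pool <- function(k_states = 2, frames_per_traj = 100,
                                 n_traj = 3, separation = 8, seed = 1,
                                 state_mix = NULL,
                                 p = parse_peptide("Biotinyl-PEG2-HSTKRGHAKSRPVRG")) {
  stopifnot(k_states >= 1, k_states <= 4, frames_per_traj >= 1, n_traj >= 1)
  jitter_sd <- 120 / separation
  patterns <- list(
    rep("helix", nrow(p)),
    rep("extended", nrow(p)),
    rep("ppii", nrow(p)),
    rep(c("helix", "extended"), length.out = nrow(p))
  )[seq_len(k_states)]
  if (is.null(state_mix)) {
    state_mix <- matrix(1 / k_states, n_traj, k_states)
  }
  stopifnot(nrow(state_mix) == n_traj, ncol(state_mix) == k_states,
            all(abs(rowSums(state_mix) - 1) < 1e-8))
  topo <- build_topology(p)
  centers <- basin_centers()
  ens_list <- vector("list", n_traj)
  states <- vector("list", n_traj)
  for (tr in seq_len(n_traj)) {
    withr::with_seed(seed * 1000 + tr, {
      st <- sample.int(k_states, frames_per_traj, replace = TRUE,
                       prob = state_mix[tr, ])
      basin <- t(vapply(st, function(s) patterns[[s]], character(nrow(p))))
      phi0 <- matrix(vapply(basin, function(b) centers[[b]][1], numeric(1)),
                     frames_per_traj, nrow(p))
      psi0 <- matrix(vapply(basin, function(b) centers[[b]][2], numeric(1)),
                     frames_per_traj, nrow(p))
      phi <- phi0 + matrix(rnorm(length(phi0), sd = jitter_sd), nrow(phi0))
      psi <- psi0 + matrix(rnorm(length(psi0), sd = jitter_sd), nrow(psi0))
      coords <- chain_from_dihedrals(phi, psi, topo)
    })
    ens_list[[tr]] <- conformation_ensemble(coords, topo,
                                            trajectory_label = paste0("traj", tr))
    states[[tr]] <- st
  }
  pooled <- bind_ensembles(ens_list)
  attr(pooled, "state") <- unlist(states)
  pooled
}
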