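# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: masses come from elemental formulas, geometry
# from direct double-loop sums.

# Elemental-formula mass oracle: residue masses summed from IUPAC average
# atomic weights, independent of the shipped residue-mass table.
ELEMENT_MASS <- c(C = 12.011, H = 1.008, N = 14.007, O = 15.999, S = 32.06)

RESIDUE_FORMULA <- list(
  G = c(C = 2, H = 3, N = 1, O = 1),  A = c(C = 3, H = 5, N = 1, O = 1),
  S = c(C = 3, H = 5, N = 1, O = 2),  P = c(C = 5, H = 7, N = 1, O = 1),
  V = c(C = 5, H = 9, N = 1, O = 1),  T = c(C = 4, H = 7, N = 1, O = 2),
  C = c(C = 3, H = 5, N = 1, O = 1, S = 1),
  L = c(C = 6, H = 11, N = 1, O = 1), I = c(C = 6, H = 11, N = 1, O = 1),
  N = c(C = 4, H = 6, N = 2, O = 2),  D = c(C = 4, H = 5, N = 1, O = 3),
  Q = c(C = 5, H = 8, N = 2, O = 2),  K = c(C = 6, H = 12, N = 2, O = 1),
  E = c(C = 5, H = 7, N = 1, O = 3),  M = c(C = 5, H = 9, N = 1, O = 1, S = 1),
  H = c(C = 6, H = 7, N = 3, O = 1),  F = c(C = 9, H = 9, N = 1, O = 1),
  R = c(C = 6, H = 12, N = 4, O = 1), Y = c(C = 9, H = 9, N = 1, O = 2),
  W = c(C = 11, H = 10, N = 2, O = 1)
)

# PTM elemental deltas: Cit swaps NH for O on Arg; hCit adds HNCO to Lys;
# KAc adds C2H2O to Lys.
PTM_FORMULA_DELTA <- list(
  none = c(),
  Cit = c(O = 1, N = -1, H = -1),
  hCit = c(C = 1, H = 1, N = 1, O = 1),
  KAc = c(C = 2, H = 2, O = 1)
)

formula_mass <- function(counts) {
  if (!length(counts)) return(0)
  sum(ELEMENT_MASS[names(counts)] * counts)
}

# Oracle peptide mass from elemental composition (no cap support beyond
# amide = -OH +NH2).
oracle_peptide_mass <- function(one_letter, ptm = rep("none", length(one_letter)),
                                amide = FALSE) {
  res <- sum(vapply(one_letter, function(a) formula_mass(RESIDUE_FORMULA[[a]]),
                    numeric(1)))
  deltas <- sum(vapply(ptm, function(m) formula_mass(PTM_FORMULA_DELTA[[m]]),
                       numeric(1)))
  water <- formula_mass(c(H = 2, O = 1))
  amide_delta <- if (amide) {
    formula_mass(c(N = 1, H = 2)) - formula_mass(c(O = 1, H = 1))
  } else 0
  res + deltas + water + amide_delta
}

# Brute-force mass-weighted radius of gyration, explicit double loop.
oracle_rg <- function(x, m) {
  com <- c(sum(x[, 1] * m), sum(x[, 2] * m), sum(x[, 3] * m)) / sum(m)
  acc <- 0
  for (i in seq_len(nrow(x))) {
    acc <- acc + m[i] * sum((x[i, ] - com)^2)
  }
  sqrt(acc / sum(m))
}

# Exhaustive medoid search.
oracle_medoid <- function(D, members) {
  best <- members[1]; best_sum <- Inf
  for (f in members) {
    s <- sum(D[f, members])
    if (s < best_sum) { best_sum <- s; best <- f }
  }
  best
}

# Shared small fixtures.
P1_SEQ <- "Biotinyl-PEG2-HSTKRGHAKSRPVRG"
TABLE1 <- tibble::tribble(
  ~id, ~sequence, ~calculated,
  "P1", "Biotinyl-PEG2-HSTKRGHAKSRPVRG", 2216.6,
  "P2", "Biotinyl-PEG2-HSTKCitGHAKSRPVCitG", 2218.6,
  "P3", "Biotinyl-PEG2-HSThCitRGHAhCitSRPVRG", 2302.6,
  "P4", "Biotinyl-PEG2-HSTK(Ac)RGHAK(Ac)SRPVRG", 2300.7,
  "P5", "Biotinyl-PEG2-HSThCitCitGHAhCitSRPVCitG", 2304.6,
  "P6", "Biotinyl-PEG2-HSTK(Ac)CitGHAK(Ac)SRPVCitG", 2302.6,
  "P7", "Biotinyl-PEG2-HSTK(Ac)RGHAhCitSRPVRG", 2301.6,
  "P8", "Biotinyl-PEG2-HSThCitRGHAK(Ac)SRPVRG", 2301.6,
  "P9", "Biotinyl-PEG2-HSTK(Ac)CitGHAhCitSRPVCitG", 2303.6,
  "P10", "Biotinyl-PEG2-HSThCitCitGHAK(Ac)SRPVCitG", 2303.6,
  "P11", "Biotinyl-PEG2-HSTK(Ac)RGHAhCitSRPVCitG", 2302.6
)

helix_ensemble <- function(n_frames = 20, jitter_sd = 1e-6, seed = 11) {
  build_ensemble(ensemble_recipe("HSTKRGHAKSRPVRG", n_frames = n_frames,
                                 basin_weights = c(helix = 1, ppii = 0, extended = 0),
                                 jitter_sd = jitter_sd, seed = seed))
}

extended_ensemble <- function(n_frames = 20, jitter_sd = 1e-6, seed = 12) {
  build_ensemble(ensemble_recipe("HSTKRGHAKSRPVRG", n_frames = n_frames,
                                 basin_weights = c(helix = 0, ppii = 0, extended = 1),
                                 jitter_sd = jitter_sd, seed = seed))
}
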