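# Flat-bottom distance-restraint potential and ensemble violation scoring.

#' Flat-bottom restraint energy
#'
#' Piecewise potential used for NOE distance restraints in MD engines:
#' quadratic below r0, zero on the flat bottom `[r0, r1]`, quadratic
#' between r1 and r2, and linear beyond r2 with a C1-continuous junction:
#' \deqn{E(r) = \frac{1}{2}k(r-r_0)^2 \; (r<r_0);\; 0 \; (r_0\le r\le r_1);\;
#'   \frac{1}{2}k(r-r_1)^2 \; (r_1<r\le r_2);\;
#'   \frac{1}{2}k(r_2-r_1)(2r-r_2-r_1) \; (r>r_2).}
#' Very-weak restraints (r1 = r2 = 10 nm) therefore contribute no energy at
#' any physically reachable separation of a short peptide.
#'
#' @param r Distance(s), nm (>= 0).
#' @param r0,r1,r2 Bounds in nm with r0 <= r1 <= r2 (vectors recycled).
#' @param k Force constant, kJ mol^-1 nm^-2 (default 1000).
#' @return Energy in kJ/mol, vectorised.
#' @export
#' @examples
#' restraint_energy(0.30, 0.18, 0.25, 0.38)  # 1.25 kJ/mol
restraint_energy <- function(r, r0, r1, r2, k = 1000) {
  if (any(r < 0)) abort("distances must be >= 0")
  if (any(k <= 0)) abort("force constant must be > 0")
  if (any(r0 > r1 | r1 > r2)) abort("bounds must satisfy r0 <= r1 <= r2")
  n <- max(length(r), length(r0), length(r1), length(r2), length(k))
  r <- rep_len(r, n); r0 <- rep_len(r0, n); r1 <- rep_len(r1, n)
  r2 <- rep_len(r2, n); k <- rep_len(k, n)
  e <- numeric(n)
  low <- r < r0
  mid <- r > r1 & r <= r2
  hi <- r > r2
  e[low] <- 0.5 * k[low] * (r[low] - r0[low])^2
  e[mid] <- 0.5 * k[mid] * (r[mid] - r1[mid])^2
  e[hi] <- 0.5 * k[hi] * (r2[hi] - r1[hi]) * (2 * r[hi] - r2[hi] - r1[hi])
  e
}

# Resolve a restraint atom reference to per-frame coordinates (n_frames x 3).
# Pseudoatoms ("Q...") resolve to the centroid of their member protons when
# present, else to the carrying carbon (e.g. QB -> HB1/HB2 midpoint or CB).
resolve_atom_xyz <- function(ens, res, atom) {
  topo <- ens$topology
  pick <- function(names_try) {
    sel <- which(topo$residue == res & topo$atom %in% names_try)
    if (!length(sel)) return(NULL)
    if (length(sel) == 1) return(ens$coords[, sel, ])
    m <- ens$coords[, sel, , drop = FALSE]
    apply(m, c(1, 3), mean)
  }
  if (grepl("^Q", atom)) {
    stem <- sub("^Q", "H", atom)
    xyz <- pick(paste0(stem, 1:3))
    if (is.null(xyz)) xyz <- pick(sub("^Q", "C", atom))
  } else {
    xyz <- pick(atom)
  }
  if (is.null(xyz)) {
    abort(sprintf("atom %s of residue %d not found in topology", atom, res))
  }
  xyz
}

#' Score restraint violations over a conformational ensemble
#'
#' Evaluates every restraint against every frame using instantaneous
#' per-frame distances (no time- or r^-3 averaging): per restraint, the
#' mean distance, the fraction of frames beyond r1, the maximum excess over
#' r1 and the mean flat-bottom energy; plus the total mean energy over
#' restraints.
#'
#' @param ens A `conformation_ensemble`.
#' @param restraints Output of [restraint_table()] (needs `res_a`,
#'   `atom_a`, `res_b`, `atom_b`, `r0`, `r1`, `r2`).
#' @param force_constant kJ mol^-1 nm^-2 (default 1000).
#' @return Object of class `violation_report`; see [tidy.violation_report()]
#'   and [glance.violation_report()].
#' @export
violation_report <- function(ens, restraints, force_constant = 1000) {
  stopifnot(inherits(ens, "conformation_ensemble"))
  if (!nrow(restraints)) abort("empty restraint table")
  if (n_frames(ens) < 1) abort("empty ensemble")
  per <- purrr::map_dfr(seq_len(nrow(restraints)), function(i) {
    rr <- restraints[i, ]
    xa <- resolve_atom_xyz(ens, rr$res_a, rr$atom_a)
    xb <- resolve_atom_xyz(ens, rr$res_b, rr$atom_b)
    if (is.null(dim(xa))) xa <- matrix(xa, nrow = 1)
    if (is.null(dim(xb))) xb <- matrix(xb, nrow = 1)
    d <- sqrt(rowSums((xa - xb)^2))
    e <- restraint_energy(d, rr$r0, rr$r1, rr$r2, force_constant)
    tibble(
      res_a = rr$res_a, atom_a = rr$atom_a,
      res_b = rr$res_b, atom_b = rr$atom_b,
      strength = rr$strength,
      mean_distance = mean(d),
      violation_fraction = mean(d > rr$r1),
      max_excess = max(c(0, d - rr$r1)),
      mean_energy = mean(e)
    )
  })
  structure(
    list(per_restraint = per,
         total_mean_energy = sum(per$mean_energy),
         n_frames = n_frames(ens),
         force_constant = force_constant),
    class = "violation_report"
  )
}

#' Tidy a violation report into its per-restraint table
#'
#' @param x A `violation_report`.
#' @param ... Unused.
#' @return Per-restraint tibble.
#' @method tidy violation_report
#' @export
tidy.violation_report <- function(x, ...) x$per_restraint

#' One-row summary of a violation report
#'
#' @param x A `violation_report`.
#' @param ... Unused.
#' @return Tibble with restraint counts, violated count (any frame beyond
#'   r1) and total mean energy.
#' @method glance violation_report
#' @export
glance.violation_report <- function(x, ...) {
  tibble(
    n_restraints = nrow(x$per_restraint),
    n_frames = x$n_frames,
    n_violated = sum(x$per_restraint$violation_fraction > 0),
    mean_violation_fraction = mean(x$per_restraint$violation_fraction),
    total_mean_energy = x$total_mean_energy
  )
}

#' @export
print.violation_report <- function(x, ...) {
  cat(sprintf(
    "<violation_report> %d restraints x %d frames; %d violated; total mean energy %.3f kJ/mol\n",
    nrow(x$per_restraint), x$n_frames,
    sum(x$per_restraint$violation_fraction > 0), x$total_mean_energy
  ))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
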