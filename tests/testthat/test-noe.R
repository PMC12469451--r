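test_that("volume calibration follows the inverse-sixth-power law", {
  peaks <- tibble::tibble(volume = c(100, 100 / 64, 50, 10, 800))
  cal <- calibrate_distances(peaks, ref_volume = 100, ref_distance = 1.78)
  expect_equal(cal$distance[1], 1.78)            # identity at the reference
  expect_equal(cal$distance[2], 2 * 1.78)        # 64-fold weaker -> doubled
  # brute-force sixth-root oracle
  expect_equal(cal$distance, 1.78 * (100 / peaks$volume)^(1 / 6),
               tolerance = 1e-9)
  # strictly decreasing in volume
  v <- sort(peaks$volume)
  d <- calibrate_distances(tibble::tibble(volume = v), 100, 1.78)$distance
  expect_true(all(diff(d) < 0))
  expect_error(calibrate_distances(tibble::tibble(volume = c(1, -2)), 100, 1.78),
               "> 0")
})

test_that("strength classes nest with inclusive upper edges", {
  expect_equal(classify_strength(c(2.6, 2.8, 2.81, 3.8, 4.2, 5.0, 5.4)),
               c("strong", "strong", "medium", "medium", "weak", "weak",
                 "very_weak"))
  # monotone non-decreasing class with distance
  r <- seq(0.5, 8, by = 0.1)
  lv <- c("strong", "medium", "weak", "very_weak")
  idx <- match(classify_strength(r), lv)
  expect_true(all(diff(idx) >= 0))
})

test_that("pseudoatom corrections are per end and typed by group", {
  expect_equal(pseudoatom_correction("HA", "A"), 0)
  expect_equal(pseudoatom_correction("QB", "S"), 1.0)   # methylene
  expect_equal(pseudoatom_correction("QB", "A"), 1.0)   # alanine methyl
  expect_equal(pseudoatom_correction("QD1", "L"), 1.0)  # leucine methyl
  expect_equal(pseudoatom_correction("QD", "F"), 2.0)   # aromatic ring
  # both-ends additivity happens in the pipeline; emulate it here
  both <- pseudoatom_correction(c("QB", "QG"), c("S", "K"))
  expect_equal(sum(both), 2.0)
})

test_that("bound construction reproduces the class table and its rules", {
  b <- build_restraint(c("strong", "medium", "weak", "very_weak"))
  expect_equal(b$r0, c(0.18, 0.18, 0.18, 0.55))
  expect_equal(b$r1, c(0.25, 0.33, 0.55, 10))
  expect_equal(b$r2, c(0.38, 0.50, 0.83, 10))
  # the 50%-increase rule, rounded to 2 decimals in nm
  expect_equal(b$r2[1:3], round(1.5 * b$r1[1:3], 2))
  expect_true(all(b$r0 <= b$r1 & b$r1 <= b$r2))

  heavy <- build_restraint("weak", hydrogen_available = FALSE)
  expect_equal(heavy$r0, 0.18 + 0.11)
  expect_equal(heavy$r1, 0.55 + 0.11)
  expect_equal(heavy$r2, 0.83 + 0.11)
  expect_true(heavy$heavy_atom_offset_applied)
  # very weak keeps its unbounded upper limit under the fallback
  vw <- build_restraint("very_weak", hydrogen_available = FALSE)
  expect_equal(c(vw$r1, vw$r2), c(10, 10))
  expect_error(build_restraint("mild"), "unknown strength")
})

test_that("the full restraint pipeline round-trips planted classes", {
  p <- parse_peptide("HSTKRGHAKSRPVRG")
  expect_equal(nrow(restraint_table(tibble::tibble(res_a = integer(),
                                                   atom_a = character(),
                                                   res_b = integer(),
                                                   atom_b = character(),
                                                   volume = double()), p)), 0)

  ens <- helix_ensemble(n_frames = 10)
  peaks <- forward_noe(ens, seed = 4)
  rt <- restraint_table(peaks, p)
  expect_equal(nrow(rt), nrow(peaks))
  # noise-free: effective distances recovered essentially exactly, so the
  # planted class (from the known d_eff) matches the assigned class always
  expect_equal(rt$strength, classify_strength(peaks$d_eff))
  expect_true(all(rt$r0 <= rt$r1 & rt$r1 <= rt$r2))
  expect_true(all(rt$r2 == round(1.5 * rt$r1, 2) | rt$strength == "very_weak"))
  # order preserved
  expect_equal(rt$volume, peaks$volume)
  # a peak weak enough falls into very_weak with the unbounded upper bound
  faint <- tibble::tibble(res_a = 1, atom_a = "HA", res_b = 9, atom_b = "HA",
                          volume = 1e-3, is_reference = FALSE)
  ref <- peaks[peaks$is_reference, ]
  rt2 <- restraint_table(dplyr::bind_rows(faint, ref), p)
  expect_equal(rt2$strength[1], "very_weak")
  expect_equal(rt2$r1[1], 10)
  # range classes follow residue separation
  expect_equal(unique(rt$range_class[abs(rt$res_a - rt$res_b) == 1]), "sequential")
  expect_equal(unique(rt$range_class[rt$res_a == rt$res_b]), "intra")
})

test_that("gromacs export is fixed-width and deterministic", {
  rt <- tibble::tibble(res_a = c(2, 3), atom_a = c("HA", "HN"),
                       res_b = c(5, 6), atom_b = c("HN", "HA"),
                       r0 = c(0.18, 0.18), r1 = c(0.25, 0.33),
                       r2 = c(0.38, 0.50), strength = c("strong", "medium"))
  lines <- write_gromacs_restraints(rt)
  expect_identical(lines[1], "[ distance_restraints ]")
  # default atom map: a-side atoms then b-side atoms, first appearance order
  expect_identical(
    lines[3],
    "     1      3     1      0      1    0.180    0.250    0.380    1.0")
  expect_identical(
    lines[4],
    "     2      4     1      1      1    0.180    0.330    0.500    1.0")
  tmp <- tempfile(fileext = ".itp")
  write_gromacs_restraints(rt, tmp)
  expect_identical(readLines(tmp), lines)
})
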