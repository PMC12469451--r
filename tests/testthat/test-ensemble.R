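test_that("equilibration discard trims the head of each trajectory", {
  ens <- build_ensemble(ensemble_recipe("HSTKR", n_frames = 200, seed = 1))
  expect_equal(n_frames(discard_equilibration(ens)), 160) # default 20%
  expect_equal(n_frames(discard_equilibration(ens, fraction = 0)), 200)
  expect_equal(n_frames(discard_equilibration(ens, ns = 40)), 160) # 1 ns/frame
  expect_error(discard_equilibration(ens, fraction = 1), "every frame")
  # pooled ensembles are trimmed per trajectory
  a <- build_ensemble(ensemble_recipe("HSTKR", n_frames = 50, seed = 2))
  b <- build_ensemble(ensemble_recipe("HSTKR", n_frames = 100, seed = 3))
  b$trajectory_label <- rep("traj2", 100)
  pool <- bind_ensembles(list(a, b))
  trimmed <- discard_equilibration(pool, fraction = 0.2)
  expect_equal(as.integer(table(trimmed$trajectory_label)[c("traj1", "traj2")]),
               c(40L, 80L))
})

test_that("radius of gyration matches closed forms and a brute-force oracle", {
  topo2 <- tibble::tibble(atom = c("X1", "X2"), element = "C",
                          residue = c(1L, 2L), mass = c(1, 1),
                          residue_code = "G")
  # all atoms at a point -> 0; two equal masses 1 nm apart -> 0.5 nm
  co <- array(0, c(1, 2, 3)); co[1, 2, 1] <- 1
  ens2 <- conformation_ensemble(co, topo2)
  expect_equal(radius_of_gyration(ens2)$rg, 0.5)
  co0 <- array(0.3, c(1, 2, 3))
  expect_equal(radius_of_gyration(conformation_ensemble(co0, topo2))$rg, 0)

  withr::with_seed(9, {
    topo <- tibble::tibble(atom = paste0("A", 1:10), element = "C",
                           residue = 1L, mass = runif(10, 1, 16),
                           residue_code = "G")
    co <- array(rnorm(10 * 3), c(1, 10, 3))
    ens <- conformation_ensemble(co, topo)
    expect_equal(radius_of_gyration(ens)$rg, oracle_rg(co[1, , ], topo$mass),
                 tolerance = 1e-12)
    # invariance under rigid motion
    ang <- runif(3, 0, 2 * pi)
    Rz <- matrix(c(cos(ang[1]), -sin(ang[1]), 0, sin(ang[1]), cos(ang[1]), 0,
                   0, 0, 1), 3, 3)
    moved <- co
    moved[1, , ] <- co[1, , ] %*% Rz + matrix(rnorm(3), 10, 3, byrow = TRUE)
    expect_equal(radius_of_gyration(conformation_ensemble(moved, topo))$rg,
                 radius_of_gyration(ens)$rg, tolerance = 1e-12)
  })
})

test_that("dihedral windows and the min-run rule assign secondary structure", {
  hel <- helix_ensemble(n_frames = 5)
  ss <- assign_secondary_structure(hel)
  expect_true(all(ss$ss[ss$residue %in% 2:14] == "H"))
  expect_true(all(ss$ss[ss$residue %in% c(1, 15)] == "C")) # terminals

  ext <- extended_ensemble(n_frames = 5)
  ss_e <- assign_secondary_structure(ext)
  expect_true(all(ss_e$ss[ss_e$residue %in% 2:14] == "E"))

  # alternating basins, run length 1 -> all C under the min-run rule
  w <- matrix(0, 15, 3, dimnames = list(NULL, c("helix", "ppii", "extended")))
  w[seq(1, 15, 2), "helix"] <- 1
  w[seq(2, 15, 2), "extended"] <- 1
  alt <- build_ensemble(ensemble_recipe("HSTKRGHAKSRPVRG", n_frames = 3,
                                        basin_weights = w, jitter_sd = 1e-6,
                                        seed = 5))
  expect_true(all(assign_secondary_structure(alt)$ss == "C"))
})

test_that("secondary-structure populations are normalised with block SEM", {
  hel <- helix_ensemble(n_frames = 10)
  pop <- ss_population(hel)
  sums <- pop %>% dplyr::group_by(residue) %>%
    dplyr::summarise(s = sum(fraction))
  expect_equal(sums$s, rep(1, 15))
  expect_true(all(pop$sem >= 0 | is.na(pop$sem)))
  expect_equal(pop$fraction[pop$residue == 7 & pop$ss == "H"], 1)
  expect_equal(pop$sem[pop$residue == 7 & pop$ss == "H"], 0)

  # 50/50 planted helix/extended mixture recovered within 3 block SEM
  mix <- build_ensemble(ensemble_recipe(
    "HSTKRGHAKSRPVRG", n_frames = 600,
    basin_weights = c(helix = 0.5, ppii = 0, extended = 0.5),
    jitter_sd = 2, seed = 8))
  popm <- ss_population(mix)
  h7 <- popm[popm$residue == 7 & popm$ss == "H", ]
  expect_lt(abs(h7$fraction - 0.5), 3 * h7$sem + 1e-9)
})

test_that("contact maps are frequencies with masked diagonal band", {
  hel <- helix_ensemble(n_frames = 5)
  cm <- contact_map(hel, cutoff = 0.55)
  expect_true(all(cm$frequency >= 0 & cm$frequency <= 1))
  expect_true(all(cm$res_j - cm$res_i >= 2))
  # monotone non-decreasing in the cutoff
  cm2 <- contact_map(hel, cutoff = 0.7)
  expect_true(all(cm2$frequency >= cm$frequency))

  # helical ensembles are enriched in i,i+3 / i,i+4 contacts vs extended
  ext <- extended_ensemble(n_frames = 5)
  prev_h <- contact_prevalence(contact_map(hel, cutoff = 0.55))
  prev_e <- contact_prevalence(contact_map(ext, cutoff = 0.55))
  hel34 <- mean(prev_h$mean_frequency[prev_h$offset %in% c(3, 4)])
  ext34 <- mean(prev_e$mean_frequency[prev_e$offset %in% c(3, 4)])
  expect_gt(hel34, ext34)
  # a fully extended chain has no mid/long-range contacts at 0.5 nm
  cm_e <- contact_map(ext, cutoff = 0.5, min_separation = 3)
  expect_true(all(cm_e$frequency == 0))
  expect_error(contact_map(hel, cutoff = -1), "> 0")
})
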