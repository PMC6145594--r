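test_that("RMSF is zero on a static trajectory", {
  st <- build_synthetic_dimer(generator_params())
  r <- rmsf(static_trajectory(st$xyz, 5), st)
  expect_true(all(r$rmsf_A < 1e-10))
})

test_that("isotropic per-coordinate noise recovers RMSF = sigma * sqrt(3)", {
  ## four fixed anchors + one free atom with iid N(0, sigma^2) per coordinate
  sigma <- 0.8
  base <- rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0), c(0, 0, 10), c(5, 5, 5))
  st <- toy_structure(base)
  nf <- 5000
  set.seed(9)
  coords <- array(rep(base, nf), dim = c(5, 3, nf))
  coords[5, , ] <- coords[5, , ] + matrix(rnorm(3 * nf, sd = sigma), 3, nf)
  traj <- eef_trajectory(coords)
  r <- rmsf(traj, st, fit_selection = selection_spec("anchors", residues = 1:4))
  free <- r$rmsf_A[r$residue_index == 5]
  expect_lt(abs(free - sigma * sqrt(3)) / (sigma * sqrt(3)), 0.05)
  expect_true(all(r$rmsf_A[r$residue_index != 5] < 1e-10))
})

test_that("RMSF is invariant under a global rigid transform of every frame", {
  p <- quick_params(seed = 10)
  st <- build_synthetic_dimer(p)
  traj <- generate_trajectory(st, p)$trajectory
  r1 <- rmsf(traj, st)
  R <- rot_axis(c(1, 2, 3), 1.1); tr <- c(30, -12, 5)
  moved <- eef_trajectory(lapply(seq_len(n_frames(traj)),
                                 function(i) apply_rigid(frame_coords(traj, i), R, tr)))
  r2 <- rmsf(moved, st)
  expect_lt(max(abs(r1$rmsf_A - r2$rmsf_A)), 1e-8)
})

test_that("loop residues fluctuate above core residues at 4x sigma", {
  p <- generator_params(n_frames = 300, ou_sigma_core = 0.4, ou_sigma_loop = 1.6,
                        seed = 12)
  st <- build_synthetic_dimer(p)
  traj <- generate_trajectory(st, p)$trajectory
  r <- rmsf(traj, st)
  a <- st$atoms[st$atoms$atom_name == "CA", ]
  key <- paste(r$monomer, r$residue_index)
  flex <- paste(a$monomer, a$residue_index)[a$ss_class != "helix"]
  core <- paste(a$monomer, a$residue_index)[a$ss_class == "helix"]
  expect_gt(min(r$rmsf_A[key %in% flex]), max(r$rmsf_A[key %in% core]))
})

test_that("delta-RMSF is exactly zero on identity and antisymmetric", {
  p <- quick_params(seed = 13)
  st <- build_synthetic_dimer(p)
  r <- rmsf(generate_trajectory(st, p)$trajectory, st)
  d0 <- delta_rmsf(r, r)
  expect_true(all(d0$delta_rmsf_A == 0))
  r2 <- r; r2$rmsf_A <- r$rmsf_A * 1.3 + 0.1
  expect_identical(delta_rmsf(r, r2)$delta_rmsf_A, -delta_rmsf(r2, r)$delta_rmsf_A)
  rbad <- r[-1, ]
  expect_error(delta_rmsf(r, rbad), "unmatched")
})

test_that("field exposure concentrates positive delta-RMSF on charged loops", {
  pe <- generator_params(n_frames = 400, field = field_spec("transverse_pos", 750), seed = 14)
  pa <- generator_params(n_frames = 400, seed = 15)
  st <- build_synthetic_dimer(pe)
  re <- rmsf(generate_trajectory(st, pe)$trajectory, st)
  ra <- rmsf(generate_trajectory(st, pa)$trajectory, st)
  d <- delta_rmsf(re, ra)
  a <- st$atoms
  qres <- tapply(a$charge, paste(a$monomer, a$residue_index), sum)
  key <- paste(d$monomer, d$residue_index)
  flex <- tapply(a$ss_class != "helix", paste(a$monomer, a$residue_index), any)
  charged_flex <- names(qres)[abs(qres) > 0 & flex[names(qres)]]
  core <- names(flex)[!flex]
  expect_true(all(d$delta_rmsf_A[key %in% charged_flex] > 0))
  expect_gt(mean(d$delta_rmsf_A[key %in% charged_flex]),
            mean(abs(d$delta_rmsf_A[key %in% core])))
})

test_that("labels-mode counts are constant and total to the residue count", {
  p <- generator_params()
  st <- build_synthetic_dimer(p)
  traj <- static_trajectory(st$xyz, 4)
  cnt <- ss_counts(traj, st, classifier = "labels")
  a <- st$atoms[!duplicated(paste(a2 <- st$atoms$monomer, st$atoms$residue_index)), ]
  expect_true(all(cnt$n_helix == sum(a$ss_class == "helix")))
  expect_true(all(cnt$n_sheet == sum(a$ss_class == "sheet")))
  expect_equal(nrow(cnt), 4)
})

test_that("geometric classifier calls an ideal helix helix and a strand not", {
  helix <- toy_structure(ideal_helix_ca(20))
  c1 <- ss_counts(static_trajectory(helix$xyz, 1), helix, classifier = "ca_geometry")
  expect_gte(c1$n_helix, 16)
  expect_equal(c1$n_sheet, 0)
  ## fully extended straight chain: no helix calls
  ext <- toy_structure(cbind(3.8 * (0:9), 0, 0))
  c2 <- ss_counts(static_trajectory(ext$xyz, 1), ext, classifier = "ca_geometry")
  expect_equal(c2$n_helix, 0)
  ## planar zigzag with Ca(i)-Ca(i+2) ~ 6.6 A: sheet, not helix
  n <- 8
  zig <- cbind(3.29 * (1:n), 0.95 * (-1)^(1:n), 0)
  c3 <- ss_counts(static_trajectory(zig, 1), toy_structure(zig), classifier = "ca_geometry")
  expect_equal(c3$n_helix, 0)
  expect_gte(c3$n_sheet, 3)
  ## chains shorter than 5 residues cannot be classified geometrically
  short <- toy_structure(cbind(3.8 * (0:3), 0, 0))
  expect_error(ss_counts(static_trajectory(short$xyz, 1), short, classifier = "ca_geometry"),
               "too short|need")
})
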