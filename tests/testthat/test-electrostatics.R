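test_that("a unit dipole pair gives 4.80321 D regardless of reference", {
  xyz <- rbind(c(0.5, 0, 0), c(-0.5, 0, 0))
  q <- c(1, -1)
  for (ref in c("com", "origin", "charge_centroid")) {
    d <- dipole_moment(xyz, q, reference_point = ref)
    expect_equal(d$magnitude_debye, 4.80321, tolerance = 1e-9)
    expect_equal(d$vector, c(1, 0, 0), tolerance = 1e-12)
  }
  expect_equal(dipole_moment(xyz, c(0, 0))$vector, c(0, 0, 0))
  expect_error(dipole_moment(xyz, c(1, NA)), "missing charges")
})

test_that("neutral-system dipoles are translation invariant; net charge shifts by q*dr", {
  set.seed(20)
  xyz <- matrix(rnorm(30, sd = 5), 10, 3)
  qn <- rnorm(10); qn <- qn - mean(qn)            # neutral
  d1 <- dipole_moment(xyz, qn, "origin")
  d2 <- dipole_moment(sweep(xyz, 2, c(7, -3, 11), "+"), qn, "origin")
  expect_lt(max(abs(d1$vector - d2$vector)), 1e-10)
  ## net-charged: moving the reference by dr changes the dipole by -q_net * dr
  qc <- qn + 0.5                                   # net +5 e
  da <- dipole_moment(xyz, qc, "origin")
  dr <- c(10, 0, 0)
  db_vec <- colSums((sweep(xyz, 2, dr)) * qc)      # reference shifted by +dr
  expect_equal(da$vector - db_vec, sum(qc) * dr, tolerance = 1e-9)
  ## rotation covariance: magnitude invariant, vector co-rotates
  R <- rot_axis(c(1, 2, -1), 0.8)
  dro <- dipole_moment(xyz %*% t(R), qc, "charge_centroid")
  dun <- dipole_moment(xyz, qc, "charge_centroid")
  expect_equal(dro$magnitude_debye, dun$magnitude_debye, tolerance = 1e-10 * dun$magnitude_debye)
  expect_equal(dro$vector, as.numeric(R %*% dun$vector), tolerance = 1e-9)
})

test_that("dipole series is constant on a static trajectory and grows under an aligned field", {
  p <- quick_params(seed = 21)
  st <- build_synthetic_dimer(p)
  ds <- dipole_series(static_trajectory(st$xyz, 4), st)
  expect_true(all(abs(ds$magnitude_debye - ds$magnitude_debye[1]) < 1e-9))
  ## field along +dipole axis exaggerates the charge distribution
  pe <- generator_params(n_frames = 300, field = field_spec("transverse_pos", 750), seed = 22)
  pa <- generator_params(n_frames = 300, seed = 23)
  me <- mean(dipole_series(generate_trajectory(st, pe)$trajectory, st)$magnitude_debye)
  ma <- mean(dipole_series(generate_trajectory(st, pa)$trajectory, st)$magnitude_debye)
  expect_gt(me, ma)
})

test_that("axes follow the dipole and the beta-to-alpha COM vector", {
  xyz <- rbind(c(0, 0.5, 0), c(0, -0.5, 0), c(0, 0, 40), c(0, 0, 40.5))
  st <- toy_structure(xyz, monomer = c("beta", "beta", "alpha", "alpha"),
                      charge = c(2, -2, 0, 0))
  ax <- compute_axes(st)
  expect_equal(ax$transverse, c(0, 1, 0), tolerance = 1e-9)
  expect_equal(ax$longitudinal, c(0, 0, 1), tolerance = 1e-9)
  ## negative rules are exact negations of the positive ones
  fpos <- field_spec("transverse_pos", 100)
  fneg <- field_spec("transverse_neg", 100)
  dim_st <- build_synthetic_dimer(generator_params())
  expect_equal(eeftraj:::field_direction(fneg, dim_st),
               -eeftraj:::field_direction(fpos, dim_st))
  st0 <- toy_structure(xyz, monomer = c("beta", "beta", "alpha", "alpha"))
  expect_error(compute_axes(st0), "zero dipole")
})

test_that("field unit conversion is exact and invertible", {
  expect_equal(convert_field(750, "kV/cm", "V/A"), 0.0075)
  expect_equal(convert_field(750, "kV/cm", "V/m"), 7.5e7)
  expect_equal(convert_field(0, "V/A", "kV/cm"), 0)
  x <- 123.456
  back <- convert_field(convert_field(x, "kV/cm", "V/m"), "V/m", "kV/cm")
  expect_lt(abs(back - x) / x, 1e-12)
  expect_error(convert_field(1, "kV/cm", "furlongs"), "unknown unit")
})

test_that("the 3.2 A cutoff is inclusive and strict beyond", {
  mk <- function(dist) {
    xyz <- rbind(c(0, 0, 0), c(dist, 0, 0), c(50, 50, 50), c(60, 60, 60))
    eef_structure(data.frame(atom_id = 1:4,
                             atom_name = c("NZ", "OD1", "CA", "CA"),
                             element = c("N", "O", "C", "C"),
                             monomer = "alpha", residue_index = c(1, 2, 3, 4),
                             region = NA_character_, ss_class = "coil",
                             charge = c(1, -1, 0, 0), mass = 14,
                             stringsAsFactors = FALSE), xyz)
  }
  expect_equal(nrow(salt_bridges(mk(3.1))), 1)
  expect_equal(salt_bridges(mk(3.1))$min_distance_A, 3.1)
  expect_equal(nrow(salt_bridges(mk(3.2))), 1)   # inclusive boundary
  expect_equal(nrow(salt_bridges(mk(3.3))), 0)
  expect_warning(out <- salt_bridges(toy_structure(rbind(c(0, 0, 0), c(3, 0, 0)))),
                 "no recognizable")
  expect_equal(nrow(out), 0)
  expect_error(salt_bridges(toy_structure(rbind(c(0, 0, 0), c(3, 0, 0))), strict = TRUE))
})

test_that("planted dimer bridges are recovered and match a brute-force scan", {
  st <- build_synthetic_dimer(generator_params())
  got <- salt_bridges(st)
  expect_setequal(paste(got$res_acidic, got$res_basic),
                  c("alpha:59 alpha:48", "beta:59 beta:48"))
  ## brute force: double loop over all acidic-O/basic-N atom pairs
  a <- st$atoms
  io <- which(a$atom_name %in% c("OD1", "OD2", "OE1", "OE2", "OXT"))
  iN <- which(a$atom_name %in% c("NZ", "NE", "NH1", "NH2"))
  found <- list()
  for (i in io) for (j in iN) {
    ka <- paste0(a$monomer[i], ":", a$residue_index[i])
    kb <- paste0(a$monomer[j], ":", a$residue_index[j])
    if (ka == kb) next
    dij <- sqrt(sum((st$xyz[i, ] - st$xyz[j, ])^2))
    k <- paste(ka, kb)
    if (is.null(found[[k]]) || dij < found[[k]]) found[[k]] <- dij
  }
  brute <- Filter(function(d) d <= 3.2, found)
  expect_setequal(paste(got$res_acidic, got$res_basic), names(brute))
  expect_equal(sort(got$min_distance_A), sort(unname(unlist(brute))), tolerance = 1e-12)
  ## atom ordering does not matter
  perm <- sample(nrow(a))
  st2 <- eef_structure(a[perm, ], st$xyz[perm, ])
  got2 <- salt_bridges(st2)
  expect_setequal(paste(got2$res_acidic, got2$res_basic),
                  paste(got$res_acidic, got$res_basic))
})
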