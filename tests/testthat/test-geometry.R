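# Independent oracle for line fitting: minimize summed squared perpendicular
# distances over a dense direction grid.
oracle_axis <- function(coords) {
  ctr <- colMeans(coords)
  xc <- sweep(coords, 2, ctr)
  obj <- function(ae) {
    d <- c(cos(ae[2]) * cos(ae[1]), cos(ae[2]) * sin(ae[1]), sin(ae[2]))
    sum(rowSums(xc^2)) - sum((xc %*% d)^2)
  }
  az <- seq(0, pi, length.out = 91)
  el <- seq(-pi / 2, pi / 2, length.out = 46)
  best <- c(0, 0); bv <- Inf
  for (a in az) for (e in el) {
    v <- obj(c(a, e))
    if (v < bv) { bv <- v; best <- c(a, e) }
  }
  ae <- stats::optim(best, obj, control = list(reltol = 1e-14, maxit = 2000))$par
  c(cos(ae[2]) * cos(ae[1]), cos(ae[2]) * sin(ae[1]), sin(ae[2]))
}

angle_between_lines <- function(u, v) {
  180 / pi * acos(min(1, abs(sum(u * v)) / sqrt(sum(u^2) * sum(v^2))))
}

test_that("fit_axis is exact on collinear points and sane on helices", {
  line <- cbind(0, 0, seq(0, 10, by = 2))
  ax <- fit_axis(line)
  expect_equal(abs(ax$direction[3]), 1, tolerance = 1e-12)
  expect_equal(ax$direction[3], 1)   # canonical sign follows input order
  expect_equal(ax$point, colMeans(line))
  hx <- fit_axis(ideal_helix_ca(20))
  expect_lt(angle_between_lines(hx$direction, c(0, 0, 1)), 2)
})

test_that("fit_axis matches the direction-grid oracle", {
  set.seed(16)
  for (i in 1:5) {
    pts <- rbind(c(0, 0, 0), c(4, 1, 0.5), c(8, -0.5, 1)) +
      matrix(rnorm(9, sd = 0.2), 3, 3)
    got <- fit_axis(pts)$direction
    expect_lt(angle_between_lines(got, oracle_axis(pts)), 0.5)
  }
})

test_that("fit_axis rejects degenerate clouds", {
  expect_error(fit_axis(matrix(1, 3, 3)), "coincident")
  octa <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  expect_error(fit_axis(octa), "isotropic")
  expect_error(fit_axis(matrix(c(0, 0, 0), 1, 3)), "at least 2")
})

test_that("bend angle recovers a constructed beta-core rotation", {
  st <- build_synthetic_dimer(generator_params())
  expect_equal(bend_angle(st$xyz, st), 0, tolerance = 1e-8)
  ## rotate the beta monomer by exactly 10 degrees about +y through the pivot
  a <- st$atoms
  core <- which(a$ss_class == "helix")
  pivot <- (colSums(st$xyz[intersect(core, which(a$monomer == "alpha")), ]) /
              sum(a$monomer[core] == "alpha") +
            colSums(st$xyz[intersect(core, which(a$monomer == "beta")), ]) /
              sum(a$monomer[core] == "beta")) / 2
  rot_beta <- function(deg) {
    x <- st$xyz
    ib <- which(a$monomer == "beta")
    R <- rot_axis(c(0, 1, 0), deg * pi / 180)
    x[ib, ] <- sweep(sweep(x[ib, , drop = FALSE], 2, pivot) %*% t(R), 2, pivot, "+")
    x
  }
  x10 <- rot_beta(10)
  expect_equal(bend_angle(x10, st, mode = "beta_only"), 10, tolerance = 0.2)
  ## inverse rotation gives the same folded angle
  expect_equal(bend_angle(rot_beta(-10), st, mode = "beta_only"),
               bend_angle(x10, st, mode = "beta_only"), tolerance = 0.2)
  ## the combined-line variant attenuates the applied rotation
  comb <- bend_angle(x10, st, mode = "combined")
  expect_gt(comb, 1)
  expect_lt(comb, 10 - 0.5)
  ## whole-structure rigid transforms cancel in the alpha-H7 superposition
  moved <- apply_rigid(x10, rot_axis(c(1, 1, 0), 0.7), c(12, -3, 40))
  expect_lt(abs(bend_angle(moved, st, mode = "beta_only") -
                bend_angle(x10, st, mode = "beta_only")), 1e-6)
})

test_that("noiseless generator frames carry exactly the drawn bend and elongation", {
  p <- quick_params(ou_sigma_core = 0, ou_sigma_loop = 0, diffusion_coefficient = 0,
                    bend_mean = 4, bend_sd = 1.5, elong_sd = 0.5, seed = 17)
  st <- build_synthetic_dimer(p)
  gen <- generate_trajectory(st, p)
  gt <- gen$ground_truth
  for (i in c(1, 7, 25)) {
    fr <- frame_coords(gen$trajectory, i)
    ## the helix PCA axis is tilted ~0.3 deg off the geometric helix axis
    ## (non-integer turn count), giving a theta-proportional ~2e-5 relative
    ## offset; exactness is asserted to that geometric precision
    expect_equal(bend_angle(fr, st, mode = "beta_only"), abs(gt$theta_deg[i]),
                 tolerance = 1e-4)
    expect_equal(elongation(fr, st), gt$elong_A[i], tolerance = 1e-9)
  }
})

test_that("elongation is the COM distance and is rigid-invariant", {
  xyz <- rbind(c(0, 0, 0), c(0, 0, 2), c(0, 40, 0), c(0, 40, 2))
  st <- toy_structure(xyz, monomer = c("beta", "beta", "alpha", "alpha"),
                      ss_class = "helix")
  expect_equal(elongation(xyz, st), 40)
  moved <- apply_rigid(xyz, rot_axis(c(1, 0, 1), 0.9), c(5, 5, 5))
  expect_equal(elongation(moved, st), 40, tolerance = 1e-9)
  st0 <- toy_structure(xyz, monomer = rep("alpha", 4), ss_class = "helix")
  expect_error(elongation(xyz, st0), "no atoms")
})

test_that("sample distributions have order-statistic quartiles and unit mass", {
  set.seed(18)
  x <- rnorm(500, 5, 2)
  d1 <- sample_distribution(x)
  d2 <- sample_distribution(sample(x))
  expect_identical(d1$quartiles, d2$quartiles)
  expect_identical(d1$mean, d2$mean)
  expect_true(d1$quartiles[1] <= d1$quartiles[2] && d1$quartiles[2] <= d1$quartiles[3])
  expect_lt(abs(sum(d1$density * diff(d1$breaks)) - 1), 1e-9)
  expect_equal(unname(d1$quartiles[2]), unname(stats::quantile(x, 0.5, type = 7)))
})

test_that("static probe-target distance gives a point distribution", {
  xyz <- rbind(c(0, 0, 0), c(12, 0, 0))
  st <- toy_structure(xyz)
  d <- distance_series(static_trajectory(xyz, 6), st,
                       probe_sel = selection_spec("p", residues = 2),
                       target_sel = selection_spec("t", residues = 1))
  expect_equal(d$samples, rep(12, 6))
  expect_equal(unname(d$quartiles), rep(12, 3))
  ## same seed, same trajectory: identical distributions
  p <- quick_params(seed = 19)
  stg <- build_synthetic_dimer(p)
  pr <- selection_spec("probe", monomer = "alpha", region = "H1-B2", residues = 4)
  tg <- selection_spec("H3", monomer = "alpha", region = "H3")
  g1 <- distance_series(generate_trajectory(stg, p)$trajectory, stg, pr, tg)
  g2 <- distance_series(generate_trajectory(stg, p)$trajectory, stg, pr, tg)
  expect_identical(g1$samples, g2$samples)
})

test_that("mean_structure averages fitted frames", {
  base <- rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0), c(0, 0, 10), c(5, 5, 5))
  st <- toy_structure(base)
  m0 <- mean_structure(static_trajectory(base, 3), st)
  expect_equal(m0, base, tolerance = 1e-12)
  ## two frames whose free atom is displaced symmetrically about a midpoint
  f2 <- base; f2[5, ] <- base[5, ] + c(2, 0, 0)
  f1 <- base; f1[5, ] <- base[5, ] - c(2, 0, 0)
  traj <- eef_trajectory(list(f1, f2))
  m <- mean_structure(traj, st, fit_selection = selection_spec("anchors", residues = 1:4))
  expect_equal(m[5, ], base[5, ], tolerance = 1e-12)
})

test_that("MSD is zero when static and exactly ballistic under drift", {
  base <- build_synthetic_dimer(generator_params())$xyz
  st <- build_synthetic_dimer(generator_params())
  m0 <- msd(static_trajectory(base, 10), st)
  expect_true(all(m0$msd_A2 < 1e-18))
  v <- c(0.02, -0.01, 0.005)  # A/ps
  dt <- 25
  frames <- lapply(0:19, function(k) sweep(base, 2, v * k * dt, "+"))
  md <- msd(eef_trajectory(frames), st)
  expect_equal(md$msd_A2, sum(v^2) * md$lag_ps^2, tolerance = 1e-9)
  ## single-origin variant agrees for pure drift
  ms <- msd(eef_trajectory(frames), st, origins = "single")
  expect_equal(ms$msd_A2, sum(v^2) * ms$lag_ps^2, tolerance = 1e-9)
})
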