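#' Total-least-squares line through a point cloud
#'
#' Centroid plus the dominant principal direction of the centered
#' coordinates. The direction sign is canonicalized to point from the early
#' toward the late atoms of the input ordering (so a helix axis fitted to
#' residues listed beta-to-alpha points beta-to-alpha).
#'
#' @param coords n x 3 matrix, n >= 2, not all coincident; the point cloud
#'   must have a dominant axis (relative eigengap between the first two
#'   principal variances > 1e-6).
#' @return list of class \code{eef_line}: \code{point} (centroid),
#'   \code{direction} (unit).
#' @export
fit_axis <- function(coords) {
  x <- as_xyz_matrix(coords)
  if (nrow(x) < 2) stop("need at least 2 points to fit an axis")
  ctr <- colMeans(x)
  xc <- sweep(x, 2, ctr)
  s <- svd(xc)
  if (s$d[1] < 1e-9) stop("coincident points: no axis")
  if ((s$d[1]^2 - s$d[2]^2) / s$d[1]^2 < 1e-6) {
    stop("isotropic point cloud: dominant axis ill-defined")
  }
  dir <- s$v[, 1]
  ## canonical sign: along the input-order trend
  trend <- sum((xc %*% dir) * (seq_len(nrow(x)) - (nrow(x) + 1) / 2))
  if (trend < 0) dir <- -dir
  structure(list(point = ctr, direction = as.numeric(dir)), class = "eef_line")
}

## Angle between two lines (undirected), folded to [0, 90] degrees.
line_angle_deg <- function(u, v) {
  c <- abs(sum(unit(u) * unit(v)))
  rad2deg(acos(pmin(1, c)))
}

#' Intradimer bend angle of one frame
#'
#' The study coordinates are superimposed on the reference using the
#' alpha-monomer H7 atoms only; the bend is then the intersection angle (in
#' [0, 90] degrees) between best-fit lines of the two structures. Mode
#' \code{"beta_only"} (default) fits each structure's line through its beta
#' H7 atoms -- the beta-monomer axis reorientation relative to the
#' alpha-anchored frame, which responds one-to-one to an applied intradimer
#' rotation. Mode \code{"combined"} fits one line through the union of
#' alpha-H7 and beta-H7 atoms per structure; because that line mixes the
#' anchored and the moving monomer it attenuates an applied rotation by a
#' geometry-dependent factor (see the methods vignette), and is reported
#' alongside rather than used for recovery.
#'
#' @param study_xyz frame coordinates (full topology) of the structure
#'   under study.
#' @param reference an \code{eef_structure} providing the straight
#'   reference.
#' @param structure topology of the study coordinates (defaults to
#'   \code{reference}).
#' @param mode \code{"beta_only"} or \code{"combined"}.
#' @param alphaH7_sel,betaH7_sel selections of the two H7 helices; defaults
#'   use the \code{"H7"} region labels.
#' @return angle in degrees.
#' @export
bend_angle <- function(study_xyz, reference, structure = reference,
                       mode = c("beta_only", "combined"),
                       alphaH7_sel = selection_spec("alpha H7", monomer = "alpha", region = "H7"),
                       betaH7_sel = selection_spec("beta H7", monomer = "beta", region = "H7")) {
  mode <- match.arg(mode)
  study_xyz <- as_xyz_matrix(study_xyz)
  ia_s <- resolve_selection(alphaH7_sel, structure)
  ib_s <- resolve_selection(betaH7_sel, structure)
  ia_r <- resolve_selection(alphaH7_sel, reference)
  ib_r <- resolve_selection(betaH7_sel, reference)
  fit <- kabsch_superpose(study_xyz[ia_s, , drop = FALSE], reference$xyz[ia_r, , drop = FALSE])
  moved <- apply_transform(fit, study_xyz)
  if (mode == "beta_only") {
    u <- fit_axis(moved[ib_s, , drop = FALSE])$direction
    v <- fit_axis(reference$xyz[ib_r, , drop = FALSE])$direction
  } else {
    u <- fit_axis(moved[c(ib_s, ia_s), , drop = FALSE])$direction
    v <- fit_axis(reference$xyz[c(ib_r, ia_r), , drop = FALSE])$direction
  }
  line_angle_deg(u, v)
}

#' Scalar sample distribution summary
#'
#' Mean, quartiles (linear-interpolation, inclusive convention) and a
#' normalized histogram whose densities integrate to 1.
#'
#' @param samples numeric vector.
#' @param units unit label carried in the object.
#' @param breaks histogram break specification (passed to
#'   \code{graphics::hist}).
#' @return object of class \code{eef_distribution}: \code{samples},
#'   \code{units}, \code{mean}, \code{quartiles} (Q1, median, Q3),
#'   \code{breaks}, \code{density}.
#' @export
sample_distribution <- function(samples, units = "", breaks = "Sturges") {
  samples <- as.numeric(samples)
  if (!length(samples)) stop("empty sample set")
  h <- graphics::hist(samples, breaks = breaks, plot = FALSE)
  q <- stats::quantile(samples, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  structure(list(samples = samples, units = units, mean = mean(samples),
                 quartiles = c(Q1 = q[1], median = q[2], Q3 = q[3]),
                 breaks = h$breaks, density = h$density),
            class = "eef_distribution")
}

#' @export
print.eef_distribution <- function(x, ...) {
  cat(sprintf("eef_distribution: n = %d, mean = %.3f %s, quartiles = [%.3f, %.3f, %.3f]\n",
              length(x$samples), x$mean, x$units,
              x$quartiles[1], x$quartiles[2], x$quartiles[3]))
  invisible(x)
}

#' @export
plot.eef_distribution <- function(x, main = "", xlab = NULL, ...) {
  graphics::plot(structure(list(breaks = x$breaks, density = x$density,
                                counts = x$density, xname = ""), class = "histogram"),
                 freq = FALSE, main = main, xlab = xlab %||% x$units, ...)
  graphics::abline(v = x$quartiles, col = "grey40", lty = 2)
  invisible(x)
}

#' Bend-angle distribution over a trajectory window
#'
#' @param traj an \code{eef_trajectory}.
#' @param structure topology of the trajectory.
#' @param reference straight reference \code{eef_structure}.
#' @param mode,alphaH7_sel,betaH7_sel see \code{\link{bend_angle}}.
#' @param window \code{c(t_start, t_end)} ps, half-open; NULL = all frames.
#' @return an \code{eef_distribution} (degrees) with attribute
#'   \code{series} (data.frame \code{time_ps, bend_deg}).
#' @export
bend_angle_series <- function(traj, structure, reference, mode = "beta_only",
                              alphaH7_sel = selection_spec("alpha H7", monomer = "alpha", region = "H7"),
                              betaH7_sel = selection_spec("beta H7", monomer = "beta", region = "H7"),
                              window = NULL) {
  idx <- window_frames(traj, window)
  vals <- vapply(idx, function(i) {
    bend_angle(frame_coords(traj, i), reference, structure, mode = mode,
               alphaH7_sel = alphaH7_sel, betaH7_sel = betaH7_sel)
  }, numeric(1))
  out <- sample_distribution(vals, units = "deg")
  attr(out, "series") <- data.frame(time_ps = traj$times[idx], bend_deg = vals)
  out
}

#' Monomer elongation of one frame
#'
#' Euclidean distance between the mass-weighted centers of mass of the
#' alpha-monomer and beta-monomer helix atom sets ("all alpha helices
#' atoms" of each monomer).
#'
#' @param xyz frame coordinates (full topology).
#' @param structure topology.
#' @param helix_alpha_sel,helix_beta_sel selections; defaults = all
#'   helix-class atoms of each monomer.
#' @return distance in Angstrom.
#' @export
elongation <- function(xyz, structure,
                       helix_alpha_sel = selection_spec("alpha helices", monomer = "alpha", ss_class = "helix"),
                       helix_beta_sel = selection_spec("beta helices", monomer = "beta", ss_class = "helix")) {
  xyz <- as_xyz_matrix(xyz)
  ia <- resolve_selection(helix_alpha_sel, structure)
  ib <- resolve_selection(helix_beta_sel, structure)
  m <- structure$atoms$mass
  ca <- center_of_mass(xyz[ia, , drop = FALSE], m[ia])
  cb <- center_of_mass(xyz[ib, , drop = FALSE], m[ib])
  sqrt(sum((ca - cb)^2))
}

#' Elongation distribution over a window
#'
#' @inheritParams bend_angle_series
#' @param ... passed to \code{\link{elongation}}.
#' @return an \code{eef_distribution} (A) with attribute \code{series}.
#' @export
elongation_series <- function(traj, structure, window = NULL, ...) {
  idx <- window_frames(traj, window)
  vals <- vapply(idx, function(i) elongation(frame_coords(traj, i), structure, ...), numeric(1))
  out <- sample_distribution(vals, units = "A")
  attr(out, "series") <- data.frame(time_ps = traj$times[idx], elongation_A = vals)
  out
}

#' Probe-to-target distance distribution
#'
#' Per frame, the distance from a probe point to the mass-weighted center
#' of mass of the target selection; collected into a distribution with
#' quartiles. The probe point is, per \code{probe_mode}: the probe
#' selection's mass-weighted COM (\code{"residue_com"}, default), its
#' non-CA side-chain atom (\code{"sidechain_tip"}), or its Calpha
#' (\code{"ca"}).
#'
#' @param traj an \code{eef_trajectory}.
#' @param structure topology.
#' @param probe_sel,target_sel \code{eef_selection}s.
#' @param probe_mode see above.
#' @param window optional half-open time window (ps).
#' @return an \code{eef_distribution} (A) with attribute \code{series}.
#' @export
distance_series <- function(traj, structure, probe_sel, target_sel,
                            probe_mode = c("residue_com", "sidechain_tip", "ca"),
                            window = NULL) {
  probe_mode <- match.arg(probe_mode)
  idx <- window_frames(traj, window)
  ip <- resolve_selection(probe_sel, structure)
  if (probe_mode == "sidechain_tip") {
    ip <- ip[structure$atoms$atom_name[ip] != "CA"]
    if (!length(ip)) stopf("selection '%s' has no side-chain atom", probe_sel$name)
  } else if (probe_mode == "ca") {
    ip <- ip[structure$atoms$atom_name[ip] == "CA"]
    if (!length(ip)) stopf("selection '%s' has no CA atom", probe_sel$name)
  }
  it <- resolve_selection(target_sel, structure)
  m <- structure$atoms$mass
  vals <- vapply(idx, function(i) {
    fr <- frame_coords(traj, i)
    p <- center_of_mass(fr[ip, , drop = FALSE], m[ip])
    t <- center_of_mass(fr[it, , drop = FALSE], m[it])
    sqrt(sum((p - t)^2))
  }, numeric(1))
  out <- sample_distribution(vals, units = "A")
  attr(out, "series") <- data.frame(time_ps = traj$times[idx], distance_A = vals)
  out
}

#' Superposed mean structure over a window
#'
#' Each window frame is superimposed on the first window frame via
#' \code{fit_selection}; coordinates are then averaged atom-wise.
#'
#' @param traj an \code{eef_trajectory}.
#' @param structure topology.
#' @param fit_selection default all Calpha.
#' @param window optional half-open time window (ps), >= 1 frame.
#' @return n x 3 coordinate matrix.
#' @export
mean_structure <- function(traj, structure, fit_selection = ca_selection(),
                           window = NULL) {
  idx <- window_frames(traj, window, min_frames = 1)
  fit_idx <- resolve_selection(fit_selection, structure)
  ref <- frame_coords(traj, idx[1])
  acc <- matrix(0, nrow(ref), 3)
  for (i in idx) acc <- acc + fit_frame(frame_coords(traj, i), ref, fit_idx)
  acc / length(idx)
}

#' Mean squared displacement of a selection's center of mass
#'
#' MSD(tau) = <|r_com(t + tau) - r_com(t)|^2>, averaged over all valid time
#' origins (or only t = first window frame with
#' \code{origins = "single"}).
#'
#' @param traj an \code{eef_trajectory}.
#' @param structure topology.
#' @param selection atoms whose COM is tracked (default: all atoms).
#' @param window optional half-open time window (ps), >= 2 frames.
#' @param max_lag largest lag in frames (default: half the window).
#' @param origins \code{"sliding"} (default) or \code{"single"}.
#' @return data.frame \code{lag_ps, msd_A2}.
#' @export
msd <- function(traj, structure, selection = NULL, window = NULL,
                max_lag = NULL, origins = c("sliding", "single")) {
  origins <- match.arg(origins)
  idx <- window_frames(traj, window, min_frames = 2)
  sel <- if (is.null(selection)) seq_len(n_atoms(structure)) else resolve_selection(selection, structure)
  m <- structure$atoms$mass[sel]
  com <- t(vapply(idx, function(i) center_of_mass(frame_coords(traj, i)[sel, , drop = FALSE], m),
                  numeric(3)))
  nfr <- nrow(com)
  max_lag <- min(max_lag %||% (nfr %/% 2), nfr - 1)
  lags <- seq_len(max_lag)
  vals <- vapply(lags, function(L) {
    if (origins == "single") {
      sum((com[1 + L, ] - com[1, ])^2)
    } else {
      d <- com[(1 + L):nfr, , drop = FALSE] - com[1:(nfr - L), , drop = FALSE]
      mean(rowSums(d^2))
    }
  }, numeric(1))
  dtimes <- traj$times[idx]
  data.frame(lag_ps = dtimes[1 + lags] - dtimes[1], msd_A2 = vals)
}

#' Diffusion coefficient from an MSD curve
#'
#' Straight-line fit (with intercept) of MSD(tau) over the given lag range;
#' the Einstein relation in three dimensions gives D = slope / 6.
#'
#' @param msd_df data.frame from \code{\link{msd}}.
#' @param lag_range optional \code{c(min, max)} lag (ps) to fit.
#' @return list \code{slope} (A^2/ps), \code{intercept}, \code{D} (A^2/ps).
#' @export
msd_diffusion <- function(msd_df, lag_range = NULL) {
  d <- msd_df
  if (!is.null(lag_range)) d <- d[d$lag_ps >= lag_range[1] & d$lag_ps <= lag_range[2], ]
  if (nrow(d) < 2) stop("need at least 2 lags to fit")
  fit <- stats::lm(msd_A2 ~ lag_ps, data = d)
  co <- stats::coef(fit)
  list(slope = unname(co[2]), intercept = unname(co[1]), D = unname(co[2]) / 6)
}
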