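#' Weighted RMSD between two coordinate sets
#'
#' \code{sqrt(sum(w_i |a_i - b_i|^2) / sum(w_i))}, symmetric in its
#' arguments. No fitting is performed.
#'
#' @param coords_a,coords_b n x 3 matrices (A).
#' @param weights optional non-negative per-atom weights (default uniform).
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(coords_a, coords_b, weights = NULL) {
  a <- as_xyz_matrix(coords_a); b <- as_xyz_matrix(coords_b)
  if (nrow(a) != nrow(b)) stopf("coordinate sets differ in length (%d vs %d)", nrow(a), nrow(b))
  w <- weights %||% rep(1, nrow(a))
  if (length(w) != nrow(a)) stop("weights length mismatch")
  sqrt(sum(w * rowSums((a - b)^2)) / sum(w))
}

#' Kabsch optimal rigid-body superposition
#'
#' Finds the proper rotation and translation minimizing the weighted RMSD of
#' \code{mobile} onto \code{reference} by SVD of the weighted covariance
#' matrix. A reflection solution (det = -1) is corrected by flipping the
#' sign of the smallest singular vector, so the result is always a proper
#' rotation. The fitted mobile coordinates are
#' \code{mobile \%*\% t(rotation) + translation} (row-vector convention).
#'
#' @param mobile,reference n x 3 matrices with n >= 3 non-collinear points.
#' @param weights optional per-atom weights (default uniform).
#' @return list of class \code{eef_superposition}: \code{rotation} (3 x 3,
#'   det +1), \code{translation}, \code{rmsd_after} (A), \code{n_atoms_fit}.
#' @export
kabsch_superpose <- function(mobile, reference, weights = NULL) {
  m <- as_xyz_matrix(mobile); r <- as_xyz_matrix(reference)
  if (nrow(m) != nrow(r)) stop("mobile and reference differ in length")
  if (nrow(m) < 3) stop("superposition needs at least 3 points")
  w <- weights %||% rep(1, nrow(m))
  w <- w / sum(w)
  cm <- colSums(m * w); cr <- colSums(r * w)
  mc <- sweep(m, 2, cm); rc <- sweep(r, 2, cr)
  ## collinearity: centered points must span >= 2 dimensions
  sv_m <- svd(mc * sqrt(w))$d
  if (sv_m[2] < 1e-8 * max(sv_m[1], 1e-12)) {
    stop("all points are collinear: rotation is under-determined")
  }
  H <- t(mc * w) %*% rc            # weighted covariance, mobile -> reference
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)        # fitted = R %*% mobile_centered (column form)
  fitted <- mc %*% t(R)
  res <- sqrt(sum(w * rowSums((fitted - rc)^2)))
  out <- list(rotation = R, translation = as.numeric(cr - R %*% cm),
              rmsd_after = res, n_atoms_fit = nrow(m))
  class(out) <- "eef_superposition"
  out
}

#' @export
print.eef_superposition <- function(x, ...) {
  ang <- rad2deg(acos(pmin(1, pmax(-1, (sum(diag(x$rotation)) - 1) / 2))))
  cat(sprintf("eef_superposition: %d atoms fit, rotation %.2f deg, rmsd_after %.4f A\n",
              x$n_atoms_fit, ang, x$rmsd_after))
  invisible(x)
}

#' Apply a superposition transform to coordinates
#'
#' @param fit an \code{eef_superposition}.
#' @param xyz n x 3 coordinates.
#' @return transformed n x 3 matrix.
#' @export
apply_transform <- function(fit, xyz) {
  xyz <- as_xyz_matrix(xyz)
  sweep(xyz %*% t(fit$rotation), 2, fit$translation, "+")
}

## Fit frame onto reference using fit_idx atoms, return whole transformed frame.
fit_frame <- function(frame, reference, fit_idx, weights = NULL) {
  fit <- kabsch_superpose(frame[fit_idx, , drop = FALSE],
                          reference[fit_idx, , drop = FALSE], weights)
  apply_transform(fit, frame)
}

#' RMSD time series after per-frame superposition
#'
#' Per frame: superimpose on the reference frame using \code{fit_selection}
#' atoms, then report RMSD over \code{measure_selection} atoms. With the
#' reference taken from the trajectory itself the series is 0 at the
#' reference frame.
#'
#' @param traj an \code{eef_trajectory}.
#' @param structure topology for selection resolution.
#' @param fit_selection,measure_selection \code{eef_selection}s; defaults:
#'   fit on all Calpha, measure = fit.
#' @param reference_frame index of the reference frame (default 1) or an
#'   n x 3 coordinate matrix.
#' @param mass_weighted use atomic masses as fit/measure weights (default
#'   FALSE, plain Calpha convention).
#' @return data.frame \code{time_ps, rmsd_A}.
#' @export
rmsd_series <- function(traj, structure, fit_selection = ca_selection(),
                        measure_selection = NULL, reference_frame = 1,
                        mass_weighted = FALSE) {
  fit_idx <- resolve_selection(fit_selection, structure)
  meas_idx <- if (is.null(measure_selection)) fit_idx else resolve_selection(measure_selection, structure)
  ref <- if (is.matrix(reference_frame)) as_xyz_matrix(reference_frame)
         else frame_coords(traj, reference_frame)
  wfit <- if (mass_weighted) structure$atoms$mass[fit_idx] else NULL
  wmea <- if (mass_weighted) structure$atoms$mass[meas_idx] else NULL
  vals <- vapply(seq_len(n_frames(traj)), function(i) {
    moved <- fit_frame(frame_coords(traj, i), ref, fit_idx, wfit)
    rmsd(moved[meas_idx, , drop = FALSE], ref[meas_idx, , drop = FALSE], wmea)
  }, numeric(1))
  data.frame(time_ps = traj$times, rmsd_A = vals)
}

#' RMSD series split by secondary-structure class
#'
#' Calpha atoms are partitioned into the rigid classes (helix + sheet)
#' versus everything else; both partitions share one fit (on
#' \code{fit_selection}) per frame, mirroring the delineation of rigid
#' versus flexible motifs. An empty partition yields an all-NA column and a
#' flag.
#'
#' @inheritParams rmsd_series
#' @return data.frame \code{time_ps, rmsd_all, rmsd_helix_sheet,
#'   rmsd_other} with attribute \code{empty_partitions}.
#' @export
rmsd_series_by_ss <- function(traj, structure, fit_selection = ca_selection(),
                              reference_frame = 1) {
  fit_idx <- resolve_selection(fit_selection, structure)
  ca_idx <- resolve_selection(ca_selection(), structure)
  rigid <- ca_idx[structure$atoms$ss_class[ca_idx] %in% c("helix", "sheet")]
  other <- setdiff(ca_idx, rigid)
  ref <- if (is.matrix(reference_frame)) as_xyz_matrix(reference_frame)
         else frame_coords(traj, reference_frame)
  one <- function(moved, idx) {
    if (!length(idx)) return(NA_real_)
    rmsd(moved[idx, , drop = FALSE], ref[idx, , drop = FALSE])
  }
  rows <- vapply(seq_len(n_frames(traj)), function(i) {
    moved <- fit_frame(frame_coords(traj, i), ref, fit_idx)
    c(one(moved, ca_idx), one(moved, rigid), one(moved, other))
  }, numeric(3))
  out <- data.frame(time_ps = traj$times, rmsd_all = rows[1, ],
                    rmsd_helix_sheet = rows[2, ], rmsd_other = rows[3, ])
  attr(out, "empty_partitions") <- c(helix_sheet = !length(rigid), other = !length(other))
  out
}
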