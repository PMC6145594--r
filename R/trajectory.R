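#' Coordinate trajectory
#'
#' An \code{eef_trajectory} stores ordered coordinate frames for a fixed
#' topology: a 3-dimensional array \code{coords[atom, xyz, frame]} in
#' Angstrom plus strictly increasing frame times in picoseconds.
#'
#' @param coords numeric array \code{n_atoms x 3 x n_frames}, or a list of
#'   n x 3 matrices.
#' @param times numeric vector of frame times (ps); defaults to
#'   \code{(0:(n_frames-1)) * frame_interval}.
#' @param frame_interval nominal spacing between saved frames (ps).
#' @return an object of class \code{eef_trajectory}.
#' @export
eef_trajectory <- function(coords, times = NULL, frame_interval = 25) {
  if (is.list(coords)) {
    mats <- lapply(coords, as_xyz_matrix)
    na <- unique(vapply(mats, nrow, 1L))
    if (length(na) != 1) stop("frames differ in atom count")
    coords <- array(unlist(mats), dim = c(na, 3, length(mats)))
  }
  if (length(dim(coords)) != 3 || dim(coords)[2] != 3) {
    stop("coords must be an n_atoms x 3 x n_frames array")
  }
  nf <- dim(coords)[3]
  if (nf < 1) stop("trajectory has zero frames")
  if (is.null(times)) times <- (seq_len(nf) - 1) * frame_interval
  if (length(times) != nf) stop("times length does not match frame count")
  if (nf > 1 && any(diff(times) <= 0)) stop("times must be strictly increasing")
  structure(list(coords = coords, times = as.numeric(times),
                 frame_interval = frame_interval),
            class = "eef_trajectory")
}

#' @export
print.eef_trajectory <- function(x, ...) {
  d <- dim(x$coords)
  cat(sprintf("eef_trajectory: %d frames x %d atoms, t = %g..%g ps (dt %g ps)\n",
              d[3], d[1], x$times[1], x$times[d[3]], x$frame_interval))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj an \code{eef_trajectory}.
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' Extract one frame as an n x 3 coordinate matrix
#' @param traj an \code{eef_trajectory}.
#' @param i frame index.
#' @export
frame_coords <- function(traj, i) traj$coords[, , i, drop = TRUE]

#' Map a half-open time window to frame indices
#'
#' The window \code{[t_start, t_end)} in ps is mapped onto frames by
#' \code{floor((t - t0) / dt)} convention: a frame belongs to the window when
#' its timestamp satisfies \code{t_start <= t < t_end}. \code{NULL} means the
#' whole trajectory.
#'
#' @param traj an \code{eef_trajectory}.
#' @param window numeric length-2 \code{c(t_start, t_end)} in ps, or NULL.
#' @param min_frames smallest admissible frame count.
#' @return integer vector of frame indices.
#' @export
window_frames <- function(traj, window = NULL, min_frames = 1) {
  if (is.null(window)) {
    idx <- seq_len(n_frames(traj))
  } else {
    if (length(window) != 2 || window[2] <= window[1]) stop("window must be c(t_start, t_end) with t_end > t_start")
    idx <- which(traj$times >= window[1] & traj$times < window[2])
  }
  if (length(idx) < min_frames) {
    stopf("window selects %d frame(s); at least %d required", length(idx), min_frames)
  }
  idx
}

#' Write a trajectory as multi-model PDB
#'
#' @param traj an \code{eef_trajectory}.
#' @param structure the matching \code{eef_structure} topology.
#' @param path output file.
#' @export
write_trajectory <- function(traj, structure, path) {
  if (dim(traj$coords)[1] != n_atoms(structure)) stop("trajectory/topology atom count mismatch")
  nf <- n_frames(traj)
  flat <- t(apply(traj$coords, 3, function(m) as.vector(t(m))))
  if (nf == 1) flat <- matrix(flat, nrow = 1)
  write_pdb_frames(structure, flat, path)
  invisible(path)
}

#' Read a coordinate trajectory
#'
#' Reads a multi-model PDB (default) or a DCD file (\code{format = "dcd"})
#' against a known topology. Frames are returned in file order; times are
#' \code{(0:(n-1)) * frame_interval} unless supplied.
#'
#' @param path trajectory file.
#' @param topology the \code{eef_structure} the frames must match.
#' @param format \code{"pdb"} (multi-model, default) or \code{"dcd"}.
#' @param frame_interval frame spacing in ps (default 25, the save interval
#'   the analyses assume).
#' @param times optional explicit frame times (ps).
#' @return an \code{eef_trajectory}.
#' @export
read_trajectory <- function(path, topology, format = c("pdb", "dcd"),
                            frame_interval = 25, times = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("no such trajectory file: %s", path)
  na <- n_atoms(topology)
  if (format == "pdb") {
    pdb <- tryCatch(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
                    error = function(e) stopf("cannot read trajectory %s: %s", path, conditionMessage(e)))
    flat <- pdb$xyz
    if (!is.matrix(flat)) flat <- matrix(flat, nrow = 1)
  } else {
    flat <- bio3d::read.dcd(path, verbose = FALSE)
    if (!is.matrix(flat)) flat <- matrix(flat, nrow = 1)
  }
  if (nrow(flat) < 1) stopf("trajectory %s has zero frames", path)
  if (ncol(flat) != 3 * na) {
    stopf("trajectory atom count (%d) does not match topology (%d)", ncol(flat) / 3, na)
  }
  coords <- array(0, dim = c(na, 3, nrow(flat)))
  for (i in seq_len(nrow(flat))) coords[, , i] <- matrix(flat[i, ], ncol = 3, byrow = TRUE)
  eef_trajectory(coords, times = times, frame_interval = frame_interval)
}
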