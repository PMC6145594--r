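#' Per-residue root-mean-square fluctuation
#'
#' RMSF_i = sqrt(<|x_i - <x_i>|^2>) over a time window, after removing
#' rigid-body motion: every window frame is superimposed (via
#' \code{fit_selection}) on the window-mean structure, with one refinement
#' pass -- fit to the plain frame average, recompute the average from the
#' fitted frames, fit again, then measure fluctuations about the final
#' mean. Deterministic.
#'
#' @param traj an \code{eef_trajectory}.
#' @param structure topology.
#' @param fit_selection atoms used for superposition (default all Calpha).
#' @param measure_selection atoms to report, one value per residue touched
#'   (default all Calpha).
#' @param window \code{c(t_start, t_end)} ps, half-open; NULL = all frames
#'   (>= 2 frames required).
#' @return data.frame \code{monomer, residue_index, rmsf_A} (a per-residue
#'   series; multiple selected atoms of one residue are averaged in the
#'   mean-square sense).
#' @export
rmsf <- function(traj, structure, fit_selection = ca_selection(),
                 measure_selection = NULL, window = NULL) {
  idx <- window_frames(traj, window, min_frames = 2)
  fit_idx <- resolve_selection(fit_selection, structure)
  meas_idx <- if (is.null(measure_selection)) resolve_selection(ca_selection(), structure)
              else resolve_selection(measure_selection, structure)
  frames <- lapply(idx, function(i) frame_coords(traj, i))
  avg <- Reduce(`+`, frames) / length(frames)
  for (pass in 1:2) {
    fitted <- lapply(frames, fit_frame, reference = avg, fit_idx = fit_idx)
    avg <- Reduce(`+`, fitted) / length(fitted)
  }
  msd_atom <- Reduce(`+`, lapply(fitted, function(f) rowSums((f - avg)^2))) / length(fitted)
  a <- structure$atoms
  key <- residue_key(a)[meas_idx]
  ms <- tapply(msd_atom[meas_idx], key, mean)
  first <- meas_idx[!duplicated(key)]
  out <- data.frame(monomer = a$monomer[first], residue_index = a$residue_index[first],
                    rmsf_A = sqrt(as.numeric(ms[key[!duplicated(key)]])),
                    stringsAsFactors = FALSE)
  out[order(out$monomer, out$residue_index), , drop = FALSE]
}

#' Field-minus-ambient change in RMSF
#'
#' Per-residue subtraction, field-exposed minus ambient: a positive value
#' means the field increased that residue's fluctuation. The two inputs
#' must cover identical residue sets.
#'
#' @param rmsf_eef,rmsf_amb data.frames from \code{\link{rmsf}}.
#' @return data.frame \code{monomer, residue_index, delta_rmsf_A}.
#' @export
delta_rmsf <- function(rmsf_eef, rmsf_amb) {
  ke <- paste(rmsf_eef$monomer, rmsf_eef$residue_index)
  ka <- paste(rmsf_amb$monomer, rmsf_amb$residue_index)
  miss <- c(setdiff(ke, ka), setdiff(ka, ke))
  if (length(miss)) stopf("residue sets differ; unmatched: %s", paste(miss, collapse = ", "))
  m <- match(ke, ka)
  data.frame(monomer = rmsf_eef$monomer, residue_index = rmsf_eef$residue_index,
             delta_rmsf_A = rmsf_eef$rmsf_A - rmsf_amb$rmsf_A[m],
             stringsAsFactors = FALSE)
}

## Helix/sheet flags per residue of one chain's ordered Calpha coordinates,
## P-SEA-style pseudo-geometry criteria on Calpha(i)-Calpha(i+k) distances.
classify_ca_chain <- function(ca) {
  n <- nrow(ca)
  if (n < 5) stop("chain too short for geometric classification (need >= 5 residues)")
  dk <- function(k) {
    d <- rep(NA_real_, n)
    i <- seq_len(n - k)
    d[i] <- sqrt(rowSums((ca[i + k, , drop = FALSE] - ca[i, , drop = FALSE])^2))
    d
  }
  d2 <- dk(2); d3 <- dk(3); d4 <- dk(4)
  helix_at <- !is.na(d3) & !is.na(d4) & d3 >= 4.8 & d3 <= 6.2 & d4 >= 5.8 & d4 <= 7.2
  helix <- rep(FALSE, n)
  run <- rle(helix_at)
  pos <- cumsum(c(1, run$lengths))
  for (r in seq_along(run$values)) {
    if (run$values[r] && run$lengths[r] >= 4) {
      helix[pos[r]:min(n, pos[r + 1] - 1 + 4)] <- TRUE   # criteria at i cover i..i+4
    }
  }
  ## sheet: extended pseudo-geometry over a 3-residue run with near-straight
  ## pseudo-dihedrals
  tau <- rep(NA_real_, n)
  if (n >= 4) {
    for (i in 2:(n - 2)) {
      b1 <- ca[i, ] - ca[i - 1, ]; b2 <- ca[i + 1, ] - ca[i, ]; b3 <- ca[i + 2, ] - ca[i + 1, ]
      n1 <- pracma_cross(b1, b2); n2 <- pracma_cross(b2, b3)
      if (sqrt(sum(n1^2)) < 1e-9 || sqrt(sum(n2^2)) < 1e-9) { tau[i] <- 180; next }
      x <- sum(n1 * n2); y <- sum(pracma_cross(n1, unit(b2)) * n2)
      tau[i] <- abs(rad2deg(atan2(y, x)))
    }
  }
  sheet_at <- !is.na(d2) & d2 >= 6.4 & d2 <= 7.4 &
    (is.na(tau) | tau >= 135)
  sheet <- rep(FALSE, n)
  run <- rle(sheet_at & !helix)
  pos <- cumsum(c(1, run$lengths))
  for (r in seq_along(run$values)) {
    if (run$values[r] && run$lengths[r] >= 2) {        # criteria at i cover i..i+2
      sheet[pos[r]:min(n, pos[r + 1] - 1 + 2)] <- TRUE
    }
  }
  sheet <- sheet & !helix
  list(helix = helix, sheet = sheet)
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

#' Per-frame counts of helix and sheet residues
#'
#' In \code{"labels"} mode the static \code{ss_class} annotations are
#' counted (a constant series). In \code{"ca_geometry"} mode each frame's
#' Calpha trace is classified per monomer from pseudo-geometry: helix when
#' Calpha(i)-Calpha(i+3) in [4.8, 6.2] A and Calpha(i)-Calpha(i+4) in
#' [5.8, 7.2] A over a 4-residue run; sheet when Calpha(i)-Calpha(i+2) in
#' [6.4, 7.4] A over a 3-residue run with near-straight pseudo-dihedrals
#' (|tau| >= 135 deg).
#'
#' @param traj an \code{eef_trajectory}.
#' @param structure topology.
#' @param classifier \code{"labels"} or \code{"ca_geometry"}.
#' @param window optional time window (ps).
#' @return data.frame \code{time_ps, n_helix, n_sheet}.
#' @export
ss_counts <- function(traj, structure, classifier = c("labels", "ca_geometry"),
                      window = NULL) {
  classifier <- match.arg(classifier)
  idx <- window_frames(traj, window)
  a <- structure$atoms
  key <- residue_key(a)
  first <- !duplicated(key)
  if (classifier == "labels") {
    nh <- sum(a$ss_class[first] == "helix")
    ns <- sum(a$ss_class[first] == "sheet")
    return(data.frame(time_ps = traj$times[idx], n_helix = nh, n_sheet = ns))
  }
  ca_idx <- resolve_selection(ca_selection(), structure)
  mono <- a$monomer[ca_idx]
  rows <- vapply(idx, function(i) {
    fr <- frame_coords(traj, i)
    tot <- c(0, 0)
    for (m in unique(mono)) {
      sel <- ca_idx[mono == m]
      sel <- sel[order(a$residue_index[sel])]
      cls <- classify_ca_chain(fr[sel, , drop = FALSE])
      tot <- tot + c(sum(cls$helix), sum(cls$sheet))
    }
    tot
  }, numeric(2))
  data.frame(time_ps = traj$times[idx], n_helix = rows[1, ], n_sheet = rows[2, ])
}
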