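#' Debye per elementary-charge Angstrom
#'
#' Conversion constant between dipole moments in e*A and Debye:
#' 1 e*A = 4.80321 D.
#' @export
DEBYE_PER_EA <- 4.80321

#' External-field specification
#'
#' A field is a direction rule, a magnitude in kV/cm, and the half-open time
#' window \code{[t_on, t_off)} (ps) during which it is applied. Direction
#' rules \code{transverse_pos}/\code{transverse_neg} follow the dimer's
#' dipole axis at the reference structure, \code{longitudinal_pos}/
#' \code{longitudinal_neg} the beta-to-alpha center-of-mass axis;
#' \code{explicit} uses \code{vector} (stored unit-normalized).
#'
#' @param direction_rule one of \code{"transverse_pos"},
#'   \code{"transverse_neg"}, \code{"longitudinal_pos"},
#'   \code{"longitudinal_neg"}, \code{"explicit"}.
#' @param magnitude field strength in kV/cm (>= 0).
#' @param window \code{c(t_on, t_off)} ps with \code{t_on < t_off}.
#' @param vector explicit direction (required iff rule is "explicit").
#' @return an object of class \code{eef_field}.
#' @export
field_spec <- function(direction_rule = c("transverse_pos", "transverse_neg",
                                          "longitudinal_pos", "longitudinal_neg",
                                          "explicit"),
                       magnitude = 0, window = c(0, Inf), vector = NULL) {
  direction_rule <- match.arg(direction_rule)
  if (magnitude < 0) stop("field magnitude must be >= 0")
  if (length(window) != 2 || window[1] >= window[2]) stop("field window needs t_on < t_off")
  if (direction_rule == "explicit") {
    if (is.null(vector)) stop("explicit direction rule requires a vector")
    vector <- unit(vector, "field vector")
  } else if (!is.null(vector)) {
    stop("vector is only meaningful with direction_rule = 'explicit'")
  }
  structure(list(direction_rule = direction_rule, magnitude = magnitude,
                 window = as.numeric(window), vector = vector),
            class = "eef_field")
}

#' @export
print.eef_field <- function(x, ...) {
  cat(sprintf("eef_field: %s, %g kV/cm, on [%g, %g) ps\n",
              x$direction_rule, x$magnitude, x$window[1], x$window[2]))
  invisible(x)
}

#' Fixed-charge dipole moment of one frame
#'
#' \code{mu = sum_i q_i (r_i - r_ref)} over the selected atoms. For a system
#' with nonzero net charge the dipole depends on the reference point, so the
#' choice is recorded in the result and defaults to the mass-weighted center
#' of mass.
#'
#' @param xyz n x 3 coordinates (A).
#' @param charges per-atom charges (e); atoms with \code{NA} charge are an
#'   error.
#' @param reference_point \code{"com"} (default), \code{"origin"} or
#'   \code{"charge_centroid"} (centroid weighted by |q|).
#' @param mass per-atom masses, needed for \code{"com"}.
#' @param time optional timestamp (ps) stored in the record.
#' @return list with \code{vector} (e*A), \code{magnitude_debye},
#'   \code{reference_point}, \code{time}.
#' @export
dipole_moment <- function(xyz, charges, reference_point = c("com", "origin", "charge_centroid"),
                          mass = NULL, time = NA_real_) {
  reference_point <- match.arg(reference_point)
  xyz <- as_xyz_matrix(xyz)
  if (length(charges) != nrow(xyz)) stop("charge vector length mismatch")
  if (anyNA(charges)) {
    stopf("missing charges for atoms: %s", paste(which(is.na(charges)), collapse = ", "))
  }
  r_ref <- switch(reference_point,
                  com = center_of_mass(xyz, mass %||% rep(1, nrow(xyz))),
                  origin = c(0, 0, 0),
                  charge_centroid = {
                    w <- abs(charges)
                    if (sum(w) == 0) c(0, 0, 0) else colSums(xyz * w) / sum(w)
                  })
  rel <- sweep(xyz, 2, r_ref)
  v <- colSums(rel * charges)
  list(vector = v, magnitude_debye = sqrt(sum(v^2)) * DEBYE_PER_EA,
       reference_point = reference_point, time = time)
}

#' Dipole-moment time series
#'
#' @param traj an \code{eef_trajectory}.
#' @param structure topology carrying charges and masses.
#' @param reference_point see \code{\link{dipole_moment}}.
#' @param window optional \code{c(t_start, t_end)} ps.
#' @return data.frame \code{time_ps, dipole_x_eA, dipole_y_eA, dipole_z_eA,
#'   magnitude_debye}.
#' @export
dipole_series <- function(traj, structure, reference_point = "com", window = NULL) {
  idx <- window_frames(traj, window)
  q <- structure$atoms$charge
  m <- structure$atoms$mass
  rows <- lapply(idx, function(i) {
    d <- dipole_moment(frame_coords(traj, i), q, reference_point, mass = m,
                       time = traj$times[i])
    c(d$time, d$vector, d$magnitude_debye)
  })
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- c("time_ps", "dipole_x_eA", "dipole_y_eA", "dipole_z_eA", "magnitude_debye")
  out
}

#' Transverse and longitudinal axes of a dimer
#'
#' The positive transverse axis is the direction of the dimer's dipole
#' moment (about the center of mass) at the reference structure; the
#' positive longitudinal axis points from the beta to the alpha monomer's
#' mass-weighted center of mass. Negative directions are exact negations.
#'
#' @param structure an \code{eef_structure} with charges and masses.
#' @return list with unit vectors \code{transverse} and \code{longitudinal}.
#' @export
compute_axes <- function(structure) {
  a <- structure$atoms
  d <- dipole_moment(structure$xyz, a$charge, "com", mass = a$mass)
  if (sqrt(sum(d$vector^2)) < 1e-9) stop("zero dipole: transverse axis undefined")
  ia <- a$monomer == "alpha"
  ib <- a$monomer == "beta"
  if (!any(ia) || !any(ib)) stop("both monomers required for the longitudinal axis")
  com_a <- center_of_mass(structure$xyz[ia, , drop = FALSE], a$mass[ia])
  com_b <- center_of_mass(structure$xyz[ib, , drop = FALSE], a$mass[ib])
  list(transverse = unit(d$vector, "dipole"), longitudinal = unit(com_a - com_b, "COM axis"))
}

## Realized unit field direction for a FieldSpec against a reference structure.
field_direction <- function(field, structure) {
  switch(field$direction_rule,
         explicit = field$vector,
         transverse_pos = compute_axes(structure)$transverse,
         transverse_neg = -compute_axes(structure)$transverse,
         longitudinal_pos = compute_axes(structure)$longitudinal,
         longitudinal_neg = -compute_axes(structure)$longitudinal)
}

#' Electric-field unit conversion
#'
#' Exact linear conversion among kV/cm, V/A and V/m
#' (1 kV/cm = 1e5 V/m; 1 V/A = 1e10 V/m).
#'
#' @param magnitude numeric value(s).
#' @param from,to units, each one of \code{"kV/cm"}, \code{"V/A"},
#'   \code{"V/m"}.
#' @export
convert_field <- function(magnitude, from, to) {
  per_vm <- c("kV/cm" = 1e5, "V/A" = 1e10, "V/m" = 1)
  if (!from %in% names(per_vm)) stopf("unknown unit '%s'", from)
  if (!to %in% names(per_vm)) stopf("unknown unit '%s'", to)
  magnitude * per_vm[[from]] / per_vm[[to]]
}

## Atom-name vocabularies for salt-bridge detection.
ACIDIC_O_NAMES <- c("OD1", "OD2", "OE1", "OE2", "OXT")
BASIC_N_NAMES <- c("NZ", "NE", "NH1", "NH2")
HIS_N_NAMES <- c("ND1", "NE2")

#' Salt-bridge detection on one frame
#'
#' A salt bridge is an acidic side-chain oxygen (Asp OD1/OD2, Glu OE1/OE2,
#' C-terminal OXT) within \code{cutoff} Angstrom (inclusive) of a basic
#' side-chain nitrogen (Lys NZ; Arg NE/NH1/NH2). Each (acidic residue, basic
#' residue) pair is reported once with the minimum O--N distance over its
#' atom pairs. Histidine nitrogens are excluded by default (neutral,
#' delta-protonated His).
#'
#' @param structure topology with atom names.
#' @param xyz coordinates to scan; defaults to the structure's own.
#' @param cutoff inclusive distance cutoff in Angstrom (default 3.2).
#' @param include_his also treat His ND1/NE2 as basic nitrogens.
#' @param strict error (TRUE) or warn and return empty (FALSE, default) when
#'   the structure carries no recognizable acidic/basic side-chain atoms.
#' @return data.frame \code{res_acidic, res_basic, min_distance_A}, sorted
#'   by distance.
#' @export
salt_bridges <- function(structure, xyz = NULL, cutoff = 3.2, include_his = FALSE,
                         strict = FALSE) {
  a <- structure$atoms
  xyz <- if (is.null(xyz)) structure$xyz else as_xyz_matrix(xyz)
  if (nrow(xyz) != nrow(a)) stop("coordinate/topology length mismatch")
  nb <- BASIC_N_NAMES
  if (include_his) nb <- c(nb, HIS_N_NAMES)
  io <- which(a$atom_name %in% ACIDIC_O_NAMES)
  iN <- which(a$atom_name %in% nb)
  empty <- data.frame(res_acidic = character(), res_basic = character(),
                      min_distance_A = numeric(), stringsAsFactors = FALSE)
  if (!length(io) || !length(iN)) {
    msg <- "structure has no recognizable acidic-O / basic-N side-chain atoms"
    if (strict) stop(msg)
    warning(msg)
    return(empty)
  }
  key <- residue_key(a)
  ## all O-N cross distances, then per residue-pair minimum
  d <- sqrt(pmax(0, outer(rowSums(xyz[io, , drop = FALSE]^2), rowSums(xyz[iN, , drop = FALSE]^2), "+") -
                   2 * xyz[io, , drop = FALSE] %*% t(xyz[iN, , drop = FALSE])))
  pair <- data.frame(res_acidic = rep(key[io], times = length(iN)),
                     res_basic = rep(key[iN], each = length(io)),
                     dist = as.vector(d), stringsAsFactors = FALSE)
  pair <- pair[pair$res_acidic != pair$res_basic, , drop = FALSE]
  if (!nrow(pair)) return(empty)
  agg <- stats::aggregate(dist ~ res_acidic + res_basic, data = pair, FUN = min)
  agg <- agg[agg$dist <= cutoff, , drop = FALSE]
  agg <- agg[order(agg$dist, agg$res_acidic), , drop = FALSE]
  rownames(agg) <- NULL
  names(agg)[3] <- "min_distance_A"
  agg
}
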