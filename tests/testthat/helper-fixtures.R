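# Shared fixture builders. Everything is generated in code; nothing is read
# from disk except files the tests themselves write to tempdir().

## A minimal hand-built structure: n CA "residues" at given coordinates.
toy_structure <- function(xyz, monomer = NULL, charge = NULL, ss_class = "coil",
                          region = NA_character_) {
  xyz <- matrix(xyz, ncol = 3, byrow = FALSE)
  n <- nrow(xyz)
  monomer <- monomer %||% rep("alpha", n)
  eef_structure(data.frame(atom_id = seq_len(n), atom_name = "CA", element = "C",
                           monomer = monomer,
                           residue_index = stats::ave(seq_len(n), monomer, FUN = seq_along),
                           region = region, ss_class = ss_class,
                           charge = charge %||% rep(0, n), mass = 12.011,
                           stringsAsFactors = FALSE),
                xyz)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Static trajectory: the same frame repeated.
static_trajectory <- function(xyz, n_frames = 5, frame_interval = 25) {
  xyz <- matrix(xyz, ncol = 3)
  eef_trajectory(array(rep(xyz, n_frames), dim = c(nrow(xyz), 3, n_frames)),
                 frame_interval = frame_interval)
}

## Ideal alpha-helix Calpha trace: rise 1.5 A, 100 deg per residue.
ideal_helix_ca <- function(n, radius = 2.3, rise = 1.5, twist_deg = 100) {
  k <- seq_len(n) - 1
  phi <- twist_deg * pi / 180 * k
  cbind(radius * cos(phi), radius * sin(phi), rise * k)
}

## Rodrigues rotation about a unit axis (local copy, independent of the
## package's internal implementation).
rot_axis <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

## Proper random rotation from QR of a Gaussian matrix.
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

apply_rigid <- function(xyz, R, t) sweep(xyz %*% t(R), 2, t, "+")

## Small generator settings used across tests (cheap but non-degenerate).
quick_params <- function(n_frames = 40, ...) generator_params(n_frames = n_frames, ...)
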