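# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

## Unit-normalize a 3-vector; error on (near-)zero length.
unit <- function(v, what = "vector") {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("cannot normalize zero-length ", what)
  v / n
}

## Rotation matrix for angle (radians) about unit axis, Rodrigues form.
rotation_about_axis <- function(axis, angle) {
  a <- unit(axis, "rotation axis")
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

## Mass-weighted center of mass of an n x 3 coordinate matrix.
center_of_mass <- function(xyz, mass = NULL) {
  xyz <- as_xyz_matrix(xyz)
  if (is.null(mass)) mass <- rep(1, nrow(xyz))
  if (length(mass) != nrow(xyz)) stop("mass length does not match coordinates")
  tm <- sum(mass)
  if (tm <= 0) stop("zero total mass")
  colSums(xyz * mass) / tm
}

## Coerce to an n x 3 numeric matrix.
as_xyz_matrix <- function(x) {
  if (is.matrix(x)) {
    if (ncol(x) != 3) stop("coordinate matrix must have 3 columns")
    storage.mode(x) <- "double"
    return(x)
  }
  x <- as.numeric(x)
  if (length(x) %% 3 != 0) stop("coordinate vector length not divisible by 3")
  matrix(x, ncol = 3, byrow = TRUE)
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

stopf <- function(...) stop(sprintf(...), call. = FALSE)

## Evaluate expr with the RNG seeded, restoring the caller's RNG state after.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}
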