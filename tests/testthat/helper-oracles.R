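# Independent brute-force oracle for optimal superposition: minimize RMSD
# over rotations by a coarse Euler-angle grid followed by Nelder-Mead
# refinement; translation handled by centroiding. Never calls the package's
# Kabsch path.
oracle_min_rmsd <- function(mobile, reference) {
  mc <- sweep(mobile, 2, colMeans(mobile))
  rc <- sweep(reference, 2, colMeans(reference))
  euler <- function(a) {
    cz <- cos(a[1]); sz <- sin(a[1]); cy <- cos(a[2]); sy <- sin(a[2])
    cx <- cos(a[3]); sx <- sin(a[3])
    Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
    Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
    Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
    Rz %*% Ry %*% Rx
  }
  obj <- function(a) sqrt(mean(rowSums((mc %*% t(euler(a)) - rc)^2)))
  grid <- seq(0, 2 * pi, length.out = 13)[-13]
  best <- c(0, 0, 0); bv <- obj(best)
  for (a1 in grid) for (a2 in grid[grid < pi + 0.1]) for (a3 in grid) {
    v <- obj(c(a1, a2, a3))
    if (v < bv) { bv <- v; best <- c(a1, a2, a3) }
  }
  stats::optim(best, obj, control = list(reltol = 1e-14, maxit = 5000))$value
}
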