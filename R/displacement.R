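#' Per-residue endpoint displacement ("final displacement")
#'
#' Distance between Calpha positions of two endpoint structures (typically
#' the final frames of two runs under fields of opposite directionality)
#' after optimal rigid superposition of frame b onto frame a via
#' \code{fit_selection}. Residues lacking a Calpha are reported as NA,
#' never as zero.
#'
#' @param xyz_a,xyz_b full-topology coordinates of the two endpoints.
#' @param structure shared topology.
#' @param fit_selection atoms used for the Kabsch fit (default: all
#'   Calpha of both monomers).
#' @return data.frame \code{monomer, residue_index, displacement_A}.
#' @export
final_displacement <- function(xyz_a, xyz_b, structure, fit_selection = ca_selection()) {
  a <- as_xyz_matrix(xyz_a); b <- as_xyz_matrix(xyz_b)
  fit_idx <- resolve_selection(fit_selection, structure)
  moved <- fit_frame(b, a, fit_idx)
  at <- structure$atoms
  key <- residue_key(at)
  first <- !duplicated(key)
  res <- data.frame(monomer = at$monomer[first], residue_index = at$residue_index[first],
                    key = key[first], stringsAsFactors = FALSE)
  ca <- which(at$atom_name == "CA")
  dca <- sqrt(rowSums((moved[ca, , drop = FALSE] - a[ca, , drop = FALSE])^2))
  dca[dca < 1e-9] <- 0   # clamp superposition round-off so identity maps to 0
  res$displacement_A <- dca[match(res$key, key[ca])]
  res$key <- NULL
  res[order(res$monomer, res$residue_index), , drop = FALSE]
}

#' Thresholded displacement vectors
#'
#' Residues whose final displacement strictly exceeds \code{threshold}
#' yield a vector from the a-structure Calpha to the fitted b-structure
#' Calpha, suitable for molecular-viewer arrows. \code{stride} exports
#' every k-th qualifying vector (a plotting decimation only).
#'
#' @inheritParams final_displacement
#' @param threshold strict displacement cutoff in Angstrom (default 2).
#' @param stride keep every \code{stride}-th vector (default 1 = all).
#' @return data.frame \code{monomer, residue_index, displacement_A, x0, y0,
#'   z0, x1, y1, z1}.
#' @export
displacement_vectors <- function(xyz_a, xyz_b, structure, fit_selection = ca_selection(),
                                 threshold = 2, stride = 1) {
  a <- as_xyz_matrix(xyz_a); b <- as_xyz_matrix(xyz_b)
  fit_idx <- resolve_selection(fit_selection, structure)
  moved <- fit_frame(b, a, fit_idx)
  at <- structure$atoms
  ca <- which(at$atom_name == "CA")
  dca <- sqrt(rowSums((moved[ca, , drop = FALSE] - a[ca, , drop = FALSE])^2))
  dca[dca < 1e-9] <- 0
  keep <- which(dca > threshold)
  if (stride > 1 && length(keep)) keep <- keep[seq(1, length(keep), by = stride)]
  i <- ca[keep]
  data.frame(monomer = at$monomer[i], residue_index = at$residue_index[i],
             displacement_A = dca[keep],
             x0 = a[i, 1], y0 = a[i, 2], z0 = a[i, 3],
             x1 = moved[i, 1], y1 = moved[i, 2], z1 = moved[i, 3],
             stringsAsFactors = FALSE)
}
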