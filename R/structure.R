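#' Annotated dimer structure
#'
#' An \code{eef_structure} bundles one set of reference coordinates with the
#' per-atom annotations every downstream stage needs: partial charge (e),
#' mass (amu), monomer assignment (\code{"alpha"}/\code{"beta"}), 1-based
#' ungapped residue index within the monomer, optional named region (e.g.
#' \code{"H7"}, \code{"H1-B2"}, \code{"M-loop"}, \code{"C-terminus"},
#' \code{"H3"}) and a static secondary-structure class.
#'
#' @param atoms data.frame with columns \code{atom_id}, \code{atom_name},
#'   \code{element}, \code{monomer}, \code{residue_index}, \code{region}
#'   (NA when unassigned), \code{ss_class}, \code{charge}, \code{mass}.
#' @param xyz numeric n x 3 matrix of coordinates in Angstrom.
#' @return an object of class \code{eef_structure}.
#' @export
eef_structure <- function(atoms, xyz) {
  xyz <- as_xyz_matrix(xyz)
  required <- c("atom_id", "atom_name", "element", "monomer", "residue_index",
                "region", "ss_class", "charge", "mass")
  missing <- setdiff(required, names(atoms))
  if (length(missing)) stopf("atoms table lacks columns: %s", paste(missing, collapse = ", "))
  if (nrow(atoms) != nrow(xyz)) stopf("atoms table (%d) and coordinates (%d) differ in length",
                                      nrow(atoms), nrow(xyz))
  if (anyDuplicated(atoms$atom_id)) stop("duplicate atom ids")
  if (!all(is.finite(xyz))) stop("non-finite coordinates")
  if (!all(is.finite(atoms$mass)) || any(atoms$mass <= 0)) stop("every atom needs mass > 0")
  if (!all(atoms$monomer %in% c("alpha", "beta"))) stop("monomer must be 'alpha' or 'beta'")
  ok_ss <- c("helix", "sheet", "coil", "turn", "3-10", "unknown")
  if (!all(atoms$ss_class %in% ok_ss)) {
    stopf("ss_class values outside {%s}", paste(ok_ss, collapse = ", "))
  }
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, xyz = xyz), class = "eef_structure")
}

#' @export
print.eef_structure <- function(x, ...) {
  a <- x$atoms
  nres <- function(m) length(unique(a$residue_index[a$monomer == m]))
  cat(sprintf("eef_structure: %d atoms, alpha %d res / beta %d res, net charge %+.1f e\n",
              nrow(a), nres("alpha"), nres("beta"), sum(a$charge)))
  reg <- sort(unique(stats::na.omit(a$region)))
  if (length(reg)) cat("  regions:", paste(reg, collapse = ", "), "\n")
  invisible(x)
}

n_atoms <- function(structure) nrow(structure$atoms)

## Residue-level key "monomer:index" in atom order, used by per-residue stages.
residue_key <- function(atoms) paste(atoms$monomer, atoms$residue_index, sep = ":")

#' Write an annotated structure to multi-model PDB + annotation sidecar
#'
#' Coordinates go to a (single-model) PDB file; charges, masses, regions and
#' secondary-structure classes go to a tab-separated sidecar keyed by
#' \code{(monomer, residue_index, atom_name)}, because the PDB format has no
#' fields for them. Monomer alpha is written as chain A, beta as chain B.
#'
#' @param structure an \code{eef_structure}.
#' @param pdb_path,annotation_path output file paths.
#' @export
write_structure <- function(structure, pdb_path, annotation_path) {
  write_pdb_frames(structure, matrix(t(structure$xyz), nrow = 1), pdb_path)
  write_annotations(structure$atoms, annotation_path)
  invisible(pdb_path)
}

write_annotations <- function(atoms, path) {
  tab <- data.frame(monomer = atoms$monomer,
                    residue_index = atoms$residue_index,
                    atom_name = atoms$atom_name,
                    element = atoms$element,
                    charge = atoms$charge,
                    mass = atoms$mass,
                    region = ifelse(is.na(atoms$region), ".", atoms$region),
                    ss_class = atoms$ss_class)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## Chain letters: alpha monomer = A, beta = B.
monomer_chain <- function(monomer) ifelse(monomer == "alpha", "A", "B")
chain_monomer <- function(chain) {
  out <- ifelse(chain == "A", "alpha", ifelse(chain == "B", "beta", NA))
  if (anyNA(out)) stop("PDB chains other than A (alpha) / B (beta) are not supported")
  out
}

## Residue name written to PDB records; charged analogs get real residue names
## so the files open cleanly in molecular viewers.
pdb_resid <- function(atoms) {
  res <- rep("ALA", nrow(atoms))
  res[atoms$atom_name == "NZ"] <- "LYS"
  res[atoms$atom_name %in% c("OD1", "OD2")] <- "ASP"
  res[atoms$atom_name %in% c("OE1", "OE2")] <- "GLU"
  ## propagate to all atoms of that residue
  key <- residue_key(atoms)
  named <- res != "ALA"
  map <- tapply(res[named], key[named], function(z) z[1])
  hit <- key %in% names(map)
  res[hit] <- unname(map[key[hit]])
  res
}

## frames_xyz: n_frames x (3*n_atoms) matrix (bio3d layout).
write_pdb_frames <- function(structure, frames_xyz, path) {
  a <- structure$atoms
  bio3d::write.pdb(file = path,
                   xyz = frames_xyz,
                   eleno = a$atom_id,
                   elety = a$atom_name,
                   resid = pdb_resid(a),
                   resno = a$residue_index,
                   chain = monomer_chain(a$monomer))
  invisible(path)
}

#' Read an annotated structure from PDB + sidecar annotation table
#'
#' Merges the first model of a PDB file with a tab-separated annotation table
#' (header \code{monomer residue_index atom_name element charge mass region
#' ss_class}). Residues the table does not cover get
#' \code{ss_class = "unknown"} and no region; atoms present in only one of
#' the two files are an error.
#'
#' @param pdb_path path to a PDB file with at least one MODEL.
#' @param annotation_path path to the sidecar TSV.
#' @return an \code{eef_structure}.
#' @export
read_structure <- function(pdb_path, annotation_path) {
  if (!file.exists(pdb_path)) stopf("no such PDB file: %s", pdb_path)
  if (!file.exists(annotation_path)) stopf("no such annotation file: %s", annotation_path)
  pdb <- bio3d::read.pdb(pdb_path, multi = FALSE, verbose = FALSE)
  at <- pdb$atom
  ann <- utils::read.delim(annotation_path, stringsAsFactors = FALSE)
  need <- c("monomer", "residue_index", "atom_name", "element", "charge", "mass",
            "region", "ss_class")
  missing <- setdiff(need, names(ann))
  if (length(missing)) stopf("annotation table lacks columns: %s", paste(missing, collapse = ", "))
  if (anyDuplicated(at$eleno)) stop("duplicate atom ids in PDB")
  key_pdb <- paste(chain_monomer(at$chain), at$resno, at$elety, sep = "|")
  key_ann <- paste(ann$monomer, ann$residue_index, ann$atom_name, sep = "|")
  if (anyDuplicated(key_ann)) stop("duplicate (monomer, residue_index, atom_name) keys in annotations")
  idx <- match(key_pdb, key_ann)
  extra <- setdiff(key_ann, key_pdb)
  if (nrow(ann) != nrow(at) || length(extra)) {
    stopf("atom count mismatch between PDB (%d atoms) and annotations (%d rows)",
          nrow(at), nrow(ann))
  }
  monomer <- chain_monomer(at$chain)
  region <- ifelse(is.na(idx), NA_character_, ann$region[idx])
  region[!is.na(region) & region == "."] <- NA_character_
  atoms <- data.frame(atom_id = at$eleno,
                      atom_name = at$elety,
                      element = ifelse(is.na(idx), substr(at$elety, 1, 1), ann$element[idx]),
                      monomer = monomer,
                      residue_index = at$resno,
                      region = region,
                      ss_class = ifelse(is.na(idx), "unknown", ann$ss_class[idx]),
                      charge = ifelse(is.na(idx), 0, ann$charge[idx]),
                      mass = ifelse(is.na(idx), 12.011, ann$mass[idx]),
                      stringsAsFactors = FALSE)
  xyz <- cbind(at$x, at$y, at$z)
  eef_structure(atoms, xyz)
}
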