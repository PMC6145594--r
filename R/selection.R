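#' Named atom selection
#'
#' A selection spec is a conjunction of filters on the annotation columns;
#' resolving it against a structure yields a deterministic, ascending-
#' \code{atom_id} index list. All filters are optional; \code{NULL} means
#' "no constraint".
#'
#' @param name label used in error messages and outputs.
#' @param monomer \code{"alpha"}, \code{"beta"} or NULL.
#' @param region region label(s), e.g. \code{"H7"}.
#' @param residues integer vector of residue indices (within the monomer
#'   filter, if any).
#' @param atom_names atom name set, e.g. \code{"CA"}.
#' @param ss_class secondary-structure class(es).
#' @return an object of class \code{eef_selection}.
#' @export
selection_spec <- function(name, monomer = NULL, region = NULL, residues = NULL,
                           atom_names = NULL, ss_class = NULL) {
  structure(list(name = name, monomer = monomer, region = region,
                 residues = residues, atom_names = atom_names,
                 ss_class = ss_class),
            class = "eef_selection")
}

#' @export
print.eef_selection <- function(x, ...) {
  parts <- Filter(Negate(is.null), x[c("monomer", "region", "residues", "atom_names", "ss_class")])
  cat(sprintf("eef_selection '%s': %s\n", x$name,
              if (length(parts)) paste(names(parts), vapply(parts, function(p) paste(p, collapse = ","), ""),
                                       sep = "=", collapse = " & ")
              else "(all atoms)"))
  invisible(x)
}

#' Resolve a selection against a structure
#'
#' @param spec an \code{eef_selection} (or a bare list with the same
#'   fields).
#' @param structure an \code{eef_structure}.
#' @return integer vector of atom row indices, ascending in \code{atom_id};
#'   resolving the same spec twice gives identical results. An empty
#'   resolution is an error naming the selection.
#' @export
resolve_selection <- function(spec, structure) {
  a <- structure$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(spec$monomer)) keep <- keep & a$monomer %in% spec$monomer
  if (!is.null(spec$region)) keep <- keep & !is.na(a$region) & a$region %in% spec$region
  if (!is.null(spec$residues)) keep <- keep & a$residue_index %in% spec$residues
  if (!is.null(spec$atom_names)) keep <- keep & a$atom_name %in% spec$atom_names
  if (!is.null(spec$ss_class)) keep <- keep & a$ss_class %in% spec$ss_class
  idx <- which(keep)
  if (!length(idx)) stopf("selection '%s' resolves to no atoms", spec$name %||% "<unnamed>")
  idx[order(a$atom_id[idx])]
}

## Convenience: Calpha atoms, optionally restricted further.
ca_selection <- function(monomer = NULL, region = NULL, ss_class = NULL,
                         name = "Calpha") {
  selection_spec(name, monomer = monomer, region = region,
                 atom_names = "CA", ss_class = ss_class)
}
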