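#' Atomic structures as tidy tibbles
#'
#' A `cadyn_structure` is a tibble of atom records — one row per atom, in file
#' order — with columns `serial`, `atom_name`, `residue_name`, `chain_id`,
#' `residue_number`, `x`, `y`, `z`, `occupancy`, `bfactor`, `element` and
#' `het` (logical, `TRUE` for HETATM records such as ligands and lipids).
#' Coordinates are in Angstrom, B-factors in Angstrom squared, and residue
#' numbers follow the author numbering of the source file (no renumbering is
#' ever applied). The `(chain_id, residue_number, atom_name)` key is unique,
#' so selection by that key is deterministic.
#'
#' @param atoms A data frame with at least `atom_name`, `residue_name`,
#'   `chain_id`, `residue_number`, `x`, `y`, `z`. Missing `serial`,
#'   `occupancy`, `bfactor`, `element`, `het` columns are filled with
#'   defaults.
#' @param label Optional character label carried in the `"label"` attribute.
#' @return A `cadyn_structure` tibble.
#' @export
new_structure <- function(atoms, label = "") {
  atoms <- as_tibble(atoms)
  defaults <- list(serial = seq_len(nrow(atoms)), occupancy = 1, bfactor = 0,
                   element = NA_character_, het = FALSE)
  for (nm in names(defaults)) {
    if (is.null(atoms[[nm]])) atoms[[nm]] <- defaults[[nm]]
  }
  required <- c("atom_name", "residue_name", "chain_id", "residue_number",
                "x", "y", "z")
  missing <- setdiff(required, names(atoms))
  if (length(missing) > 0) {
    abort(paste0("structure is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  atoms$residue_number <- as.integer(atoms$residue_number)
  atoms <- atoms[, c("serial", "atom_name", "residue_name", "chain_id",
                     "residue_number", "x", "y", "z", "occupancy", "bfactor",
                     "element", "het")]
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z))) {
    abort("structure coordinates must all be finite")
  }
  if (any(!nzchar(atoms$atom_name))) abort("atom_name must be non-empty")
  key <- paste(atoms$chain_id, atoms$residue_number, atoms$atom_name)
  if (anyDuplicated(key)) {
    abort(paste0("duplicate (chain, residue, atom) key: ",
                 key[duplicated(key)][1]))
  }
  class(atoms) <- c("cadyn_structure", class(tibble()))
  attr(atoms, "label") <- label
  atoms
}

#' @export
print.cadyn_structure <- function(x, ...) {
  lab <- attr(x, "label")
  cat(sprintf("<cadyn_structure> %d atoms (%d HETATM)%s\n",
              nrow(x), sum(x$het),
              if (nzchar(lab)) paste0(" label: ", lab) else ""))
  NextMethod()
}

#' Extract a coordinate matrix from a structure
#'
#' @param structure A [new_structure()] tibble.
#' @param atoms Atom-name filter (default `"CA"`; `NULL` keeps all atoms).
#' @param chain Optional chain filter.
#' @param residues Optional vector of residue numbers.
#' @param het Keep HETATM records? Default drops them.
#' @return Numeric matrix with one row per atom and columns x, y, z; row
#'   names are `"chain:resnum:atom"` keys.
#' @export
coords_matrix <- function(structure, atoms = "CA", chain = NULL,
                          residues = NULL, het = FALSE) {
  sel <- rep(TRUE, nrow(structure))
  if (!is.null(atoms)) sel <- sel & structure$atom_name %in% atoms
  if (!is.null(chain)) sel <- sel & structure$chain_id %in% chain
  if (!is.null(residues)) sel <- sel & structure$residue_number %in% residues
  if (!het) sel <- sel & !structure$het
  s <- structure[sel, ]
  m <- cbind(x = s$x, y = s$y, z = s$z)
  rownames(m) <- atom_key(s)
  m
}

atom_key <- function(df) {
  paste(df$chain_id, df$residue_number, df$atom_name, sep = ":")
}

#' Select a single atom by key
#'
#' @inheritParams coords_matrix
#' @param residue Residue number.
#' @param atom Atom name (default `"CA"`).
#' @return One-row structure tibble; errors when the atom is absent.
#' @export
select_atom <- function(structure, residue, atom = "CA", chain = NULL) {
  sel <- structure$residue_number == residue & structure$atom_name == atom
  if (!is.null(chain)) sel <- sel & structure$chain_id == chain
  hit <- structure[sel, ]
  if (nrow(hit) == 0) {
    abort(sprintf("atom %s of residue %d%s not found", atom, residue,
                  if (is.null(chain)) "" else paste0(" (chain ", chain, ")")))
  }
  if (nrow(hit) > 1) {
    abort(sprintf(
      "residue %d atom %s is ambiguous across chains (%s); pass `chain`",
      residue, atom, paste(unique(hit$chain_id), collapse = ", ")))
  }
  hit
}

#' Replace residue names at given positions
#'
#' Convenience for building synthetic test structures (e.g. planting
#' aromatic residues at known sites before an aromatic census).
#'
#' @inheritParams coords_matrix
#' @param residues Residue numbers to rename.
#' @param new_name 3-letter residue name to assign.
#' @export
mutate_residues <- function(structure, residues, new_name) {
  structure$residue_name[structure$residue_number %in% residues] <- new_name
  structure
}
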