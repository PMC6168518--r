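#' Coordinate trajectories
#'
#' A `cadyn_trajectory` couples a fixed atom roster with an `F x N x 3`
#' coordinate array (frames x atoms x xyz, Angstrom) and a frame interval in
#' picoseconds. The roster is a tibble with key columns `chain_id`,
#' `residue_number`, `atom_name` (plus optional `residue_name`/`element`
#' carried along for writing PDB output); every frame holds exactly one
#' coordinate triple per roster atom, in roster order.
#'
#' @param roster Tibble with `chain_id`, `residue_number`, `atom_name`.
#' @param coords Numeric array `F x N x 3`, or a list of `N x 3` matrices.
#' @param frame_interval_ps Time between saved frames, picoseconds (> 0).
#' @return A `cadyn_trajectory` object.
#' @export
new_trajectory <- function(roster, coords, frame_interval_ps = 10) {
  roster <- as_tibble(roster)
  need <- c("chain_id", "residue_number", "atom_name")
  if (!all(need %in% names(roster))) {
    abort("roster needs chain_id, residue_number, atom_name columns")
  }
  if (is.list(coords) && !is.array(coords)) {
    if (length(coords) == 0) abort("trajectory needs at least one frame")
    coords <- aperm(simplify2array(coords), c(3, 1, 2))
  }
  if (length(dim(coords)) != 3 || dim(coords)[3] != 3) {
    abort("coords must be an F x N x 3 array")
  }
  if (dim(coords)[1] < 1) abort("trajectory needs at least one frame (F >= 1)")
  if (dim(coords)[2] != nrow(roster)) {
    abort(sprintf("coords has %d atoms per frame but roster has %d",
                  dim(coords)[2], nrow(roster)))
  }
  if (!all(is.finite(coords))) abort("trajectory coordinates must be finite")
  if (!is.numeric(frame_interval_ps) || frame_interval_ps <= 0) {
    abort("frame_interval_ps must be > 0")
  }
  dimnames(coords) <- NULL
  structure(
    list(roster = roster, coords = coords,
         frame_interval_ps = as.numeric(frame_interval_ps)),
    class = "cadyn_trajectory")
}

#' @export
print.cadyn_trajectory <- function(x, ...) {
  cat(sprintf(
    "<cadyn_trajectory> %d frames x %d atoms, %.6g ps/frame (span %.6g ns)\n",
    n_frames(x), nrow(x$roster), x$frame_interval_ps,
    n_frames(x) * x$frame_interval_ps / 1000))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj A [new_trajectory()] object.
#' @export
n_frames <- function(traj) dim(traj$coords)[1]

#' Extract one frame as an N x 3 coordinate matrix
#' @inheritParams n_frames
#' @param i Frame index (1-based).
#' @export
frame_coords <- function(traj, i) {
  if (i < 1 || i > n_frames(traj)) abort("frame index out of range")
  m <- traj$coords[i, , , drop = FALSE]
  dim(m) <- dim(m)[2:3]
  colnames(m) <- c("x", "y", "z")
  m
}

#' Promote a structure to a one-frame trajectory
#' @param structure A [new_structure()] tibble.
#' @param frame_interval_ps Frame interval to declare, ps.
#' @export
as_trajectory <- function(structure, frame_interval_ps = 10) {
  m <- coords_matrix(structure, atoms = NULL, het = TRUE)
  arr <- array(0, dim = c(1, nrow(m), 3))
  arr[1, , ] <- m
  new_trajectory(structure[, c("chain_id", "residue_number", "atom_name",
                               "residue_name", "element")],
                 arr, frame_interval_ps)
}

#' Extract a frame of a trajectory as a structure
#' @inheritParams frame_coords
#' @export
frame_structure <- function(traj, i = 1) {
  m <- frame_coords(traj, i)
  r <- traj$roster
  new_structure(tibble(
    atom_name = r$atom_name,
    residue_name = roster_col(r, "residue_name", "GLY"),
    chain_id = r$chain_id, residue_number = r$residue_number,
    x = m[, 1], y = m[, 2], z = m[, 3],
    element = roster_col(r, "element", NA_character_)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Resolve roster indices for a selection
#'
#' @inheritParams n_frames
#' @param atoms Atom names to keep (default `"CA"`; `NULL` for all).
#' @param chain Optional chain filter.
#' @param residues Optional residue numbers.
#' @return Integer roster indices; errors when the selection is empty.
#' @export
roster_index <- function(traj, atoms = "CA", chain = NULL, residues = NULL) {
  r <- traj$roster
  sel <- rep(TRUE, nrow(r))
  if (!is.null(atoms)) sel <- sel & r$atom_name %in% atoms
  if (!is.null(chain)) sel <- sel & r$chain_id %in% chain
  if (!is.null(residues)) sel <- sel & r$residue_number %in% residues
  idx <- which(sel)
  if (length(idx) == 0) abort("selection matches no roster atoms")
  idx
}

## Resolve one (residue, CA) landmark atom on a roster; chain defaults to the
## single chain present, with an explicit override for two-molecule files.
resolve_residue <- function(roster, residue, chain = NULL, atom = "CA") {
  sel <- roster$residue_number == residue & roster$atom_name == atom
  if (!is.null(chain)) sel <- sel & roster$chain_id == chain
  idx <- which(sel)
  if (length(idx) == 0) {
    abort(sprintf("residue %d (atom %s%s) not resolvable on roster", residue,
                  atom, if (is.null(chain)) "" else paste0(", chain ", chain)))
  }
  if (length(idx) > 1) {
    abort(sprintf(
      "residue %d atom %s matches several chains (%s); pass `chain`",
      residue, atom,
      paste(unique(roster$chain_id[idx]), collapse = ", ")))
  }
  idx
}

## safe roster column access: tibbles warn on `$` for absent columns
roster_col <- function(r, name, default) {
  if (name %in% names(r)) r[[name]] else rep(default, length.out = nrow(r))
}
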