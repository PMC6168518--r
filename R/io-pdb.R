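#' Read a PDB file or text
#'
#' Parses the ATOM/HETATM/MODEL/ENDMDL subset of the PDB format. A
#' single-model file yields a [new_structure()] tibble; a multi-model file
#' whose models share an identical atom roster yields a
#' [new_trajectory()] with the given frame interval. HETATM records are
#' retained and flagged in the `het` column.
#'
#' Alternate locations are resolved by keeping the highest-occupancy
#' conformer (ties broken by the first listed). Insertion codes are not
#' supported and are rejected with an error. Residue numbers are the file's
#' author numbering, untouched.
#'
#' @param input Path to a PDB file, or a character scalar/vector of PDB
#'   lines.
#' @param frame_interval_ps Frame interval declared for multi-model input,
#'   picoseconds.
#' @param label Label attached to a returned structure (defaults to the file
#'   name).
#' @return A `cadyn_structure` or, for multi-model input, a
#'   `cadyn_trajectory`.
#' @export
read_pdb <- function(input, frame_interval_ps = 10, label = NULL) {
  if (length(input) == 1 && !grepl("\n", input) && file.exists(input)) {
    if (is.null(label)) label <- basename(input)
    lines <- readLines(input, warn = FALSE)
  } else {
    lines <- unlist(strsplit(input, "\n", fixed = TRUE))
    if (is.null(label)) label <- ""
  }
  is_atom <- grepl("^(ATOM|HETATM)", lines)
  if (!any(is_atom)) abort("no ATOM/HETATM records found")

  model_id <- cumsum(grepl("^MODEL", lines))
  if (model_id[1] == 0) model_id <- model_id + 1
  atom_lines <- lines[is_atom]
  atom_models <- model_id[is_atom]
  atom_lineno <- which(is_atom)

  fld <- function(from, to) trimws(substr(atom_lines, from, to))
  icode <- fld(27, 27)
  if (any(nzchar(icode))) {
    abort(sprintf("insertion codes are not supported (line %d)",
                  atom_lineno[which(nzchar(icode))[1]]))
  }
  num <- function(from, to, what) {
    v <- suppressWarnings(as.numeric(fld(from, to)))
    bad <- which(is.na(v) & nzchar(fld(from, to)))
    miss <- which(!nzchar(fld(from, to)))
    if (what %in% c("x", "y", "z") && (length(bad) || length(miss))) {
      ln <- atom_lineno[c(bad, miss)[1]]
      abort(sprintf("unparseable %s coordinate at line %d", what, ln))
    }
    if (length(bad)) v[bad] <- NA_real_
    v
  }
  atoms <- tibble(
    model = atom_models,
    serial = suppressWarnings(as.integer(fld(7, 11))),
    atom_name = fld(13, 16),
    altloc = fld(17, 17),
    residue_name = fld(18, 20),
    chain_id = fld(22, 22),
    residue_number = suppressWarnings(as.integer(fld(23, 26))),
    x = num(31, 38, "x"), y = num(39, 46, "y"), z = num(47, 54, "z"),
    occupancy = num(55, 60, "occ"), bfactor = num(61, 66, "b"),
    element = fld(77, 78),
    het = grepl("^HETATM", atom_lines))
  if (any(is.na(atoms$residue_number))) {
    abort(sprintf("unparseable residue number at line %d",
                  atom_lineno[which(is.na(atoms$residue_number))[1]]))
  }
  atoms$occupancy[is.na(atoms$occupancy)] <- 1
  atoms$bfactor[is.na(atoms$bfactor)] <- 0
  atoms$element[!nzchar(atoms$element)] <-
    guess_element(atoms$atom_name[!nzchar(atoms$element)])

  ## altloc policy: highest occupancy wins, ties to the first listed
  atoms <- atoms |>
    dplyr::group_by(.data$model, .data$chain_id, .data$residue_number,
                    .data$atom_name) |>
    dplyr::slice_max(.data$occupancy, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$model, .data$serial)
  atoms$altloc <- NULL

  models <- split(atoms, atoms$model)
  if (length(models) == 1) {
    return(new_structure(models[[1]][, -1], label = label))
  }
  key0 <- atom_key(models[[1]])
  for (k in seq_along(models)[-1]) {
    if (!identical(atom_key(models[[k]]), key0)) {
      abort(sprintf(
        "roster mismatch: model %d does not list the same atoms as model 1",
        k))
    }
  }
  coords <- array(0, dim = c(length(models), nrow(models[[1]]), 3))
  for (k in seq_along(models)) {
    coords[k, , ] <- cbind(models[[k]]$x, models[[k]]$y, models[[k]]$z)
  }
  new_trajectory(models[[1]][, c("chain_id", "residue_number", "atom_name",
                                 "residue_name", "element")],
                 coords, frame_interval_ps)
}

guess_element <- function(atom_name) {
  e <- sub("^[0-9]*", "", atom_name)
  two <- toupper(substr(e, 1, 2)) %in% c("FE", "ZN", "MG", "SE", "CL", "BR")
  ifelse(two, substr(e, 1, 2), substr(e, 1, 1))
}

#' Write a structure or trajectory as PDB text
#'
#' Trajectories are written as multi-model PDB (MODEL/ENDMDL blocks), the
#' canonical trajectory interchange format, directly viewable in standard
#' molecular viewers.
#'
#' @param x A `cadyn_structure` or `cadyn_trajectory`.
#' @param path Output file; when `NULL` the lines are returned invisibly
#'   without writing.
#' @return The character vector of PDB lines, invisibly.
#' @export
write_pdb <- function(x, path = NULL) {
  if (inherits(x, "cadyn_structure")) {
    lines <- c(pdb_atom_lines(x), "END")
  } else if (inherits(x, "cadyn_trajectory")) {
    r <- x$roster
    fake <- tibble(
      serial = seq_len(nrow(r)), atom_name = r$atom_name,
      residue_name = roster_col(r, "residue_name", "GLY"),
      chain_id = r$chain_id, residue_number = r$residue_number,
      occupancy = 1, bfactor = 0,
      element = roster_col(r, "element", guess_element(r$atom_name)),
      het = FALSE)
    lines <- unlist(lapply(seq_len(n_frames(x)), function(i) {
      m <- frame_coords(x, i)
      fr <- fake
      fr$x <- m[, 1]; fr$y <- m[, 2]; fr$z <- m[, 3]
      c(sprintf("MODEL     %4d", i), pdb_atom_lines(fr), "ENDMDL")
    }))
    lines <- c(lines, "END")
  } else {
    abort("write_pdb() expects a cadyn_structure or cadyn_trajectory")
  }
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

pdb_atom_lines <- function(df) {
  rec <- ifelse(df$het, "HETATM", "ATOM  ")
  name <- ifelse(nchar(df$atom_name) >= 4, substr(df$atom_name, 1, 4),
                 sprintf(" %-3s", df$atom_name))
  el <- df$element
  el[is.na(el)] <- guess_element(df$atom_name[is.na(el)])
  sprintf("%s%5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          rec, df$serial %% 100000L, name, df$residue_name, df$chain_id,
          df$residue_number, df$x, df$y, df$z, df$occupancy, df$bfactor,
          toupper(el))
}

#' Split a structure into its crystallographic molecules
#'
#' The molecules of an asymmetric unit ("mol A", "mol B") are the chain
#' groups of the file, in file order.
#'
#' @param structure A `cadyn_structure`.
#' @return Named list of single-chain structures (`"mol A"`, `"mol B"`, ...),
#'   HETATM records dropped.
#' @export
split_molecules <- function(structure) {
  s <- structure[!structure$het, ]
  chains <- unique(s$chain_id)
  out <- lapply(chains, function(ch) new_structure(
    s[s$chain_id == ch, ],
    label = paste0(attr(structure, "label"), " mol ", ch)))
  names(out) <- paste("mol", chains)
  out
}
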