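#' Write / read the plain-text frame table format
#'
#' The frame table is the package's bulk trajectory format: a tab-separated
#' table with columns `frame`, `chain`, `resnum`, `atomname`, `x`, `y`, `z`
#' (one row per atom per frame) preceded by a header line
#' `# cadyn-frame-table v1 frame_interval_ps=<ps>`. Coordinates are written
#' at full double precision so the round trip is lossless.
#'
#' @param traj A [new_trajectory()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_frame_table <- function(traj, path) {
  if (!inherits(traj, "cadyn_trajectory")) {
    abort("write_frame_table() expects a cadyn_trajectory")
  }
  r <- traj$roster
  f <- n_frames(traj)
  n <- nrow(r)
  tbl <- tibble(
    frame = rep(seq_len(f), each = n),
    chain = rep(r$chain_id, f),
    resnum = rep(r$residue_number, f),
    atomname = rep(r$atom_name, f),
    x = as.vector(t(traj$coords[, , 1])),
    y = as.vector(t(traj$coords[, , 2])),
    z = as.vector(t(traj$coords[, , 3])))
  header <- sprintf("# cadyn-frame-table v1 frame_interval_ps=%.17g",
                    traj$frame_interval_ps)
  writeLines(header, path)
  readr::write_tsv(tbl, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_frame_table
#' @param path_or_text Path to a frame table, or its text content.
#' @export
read_frame_table <- function(path_or_text) {
  if (length(path_or_text) == 1 && !grepl("\n", path_or_text) &&
      file.exists(path_or_text)) {
    lines <- readLines(path_or_text, warn = FALSE)
  } else {
    lines <- unlist(strsplit(path_or_text, "\n", fixed = TRUE))
  }
  if (length(lines) < 2 || !grepl("^# cadyn-frame-table v1", lines[1])) {
    abort("missing frame-table header line '# cadyn-frame-table v1 ...'")
  }
  ps <- as.numeric(sub(".*frame_interval_ps=", "", lines[1]))
  if (!is.finite(ps)) abort("header does not declare frame_interval_ps")
  tbl <- readr::read_tsv(I(paste(lines[-1], collapse = "\n")),
                         col_types = "icicddd", progress = FALSE)
  frames <- unique(tbl$frame)
  n <- sum(tbl$frame == frames[1])
  if (nrow(tbl) != n * length(frames)) {
    abort("frame table is ragged: frames differ in atom count")
  }
  first <- tbl[tbl$frame == frames[1], ]
  roster <- tibble(chain_id = first$chain, residue_number = first$resnum,
                   atom_name = first$atomname)
  coords <- array(0, dim = c(length(frames), n, 3))
  coords[, , 1] <- matrix(tbl$x, nrow = length(frames), byrow = TRUE)
  coords[, , 2] <- matrix(tbl$y, nrow = length(frames), byrow = TRUE)
  coords[, , 3] <- matrix(tbl$z, nrow = length(frames), byrow = TRUE)
  new_trajectory(roster, coords, frame_interval_ps = ps)
}
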