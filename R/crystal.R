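#' Crystal-structure geometry report
#'
#' Runs the deterministic geometry pipeline on a set of deposited crystal
#' structures of an ABC transporter, each containing two molecules
#' (chain groups) in the asymmetric unit:
#'
#' * `intra`: Ca Kabsch RMSD between mol A and mol B of each structure,
#'   over their shared residues;
#' * `cross`: Ca RMSD of each non-reference structure's mol A / mol B
#'   against the same molecule of the reference structure (first
#'   accession);
#' * `portal_angles`: the front (`G226-L215-S345`) and back
#'   (`V869-L858-S988`) bilayer-portal opening angles for every molecule,
#'   plus their average over all molecules.
#'
#' @param paths Named character vector of PDB file paths; names are the
#'   accession labels (the first is the cross-RMSD reference).
#' @param landmarks Landmark set supplying the `front`/`back` triplets.
#' @return List of tibbles `intra`, `cross`, `portal_angles`,
#'   `portal_means`.
#' @export
crystal_geometry_report <- function(paths,
                                    landmarks = default_landmarks()) {
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    abort(paste0("crystal structure file(s) not found: ",
                 paste(missing, collapse = ", ")))
  }
  if (is.null(names(paths))) {
    names(paths) <- toupper(sub("[.].*$", "", basename(paths)))
  }
  mols <- lapply(paths, function(p) split_molecules(read_pdb(p)))
  intra <- purrr::imap_dfr(mols, function(m, acc) {
    tibble(accession = acc,
           rmsd = kabsch_superpose(m[[1]], m[[2]])$rmsd)
  })
  ref <- mols[[1]]
  cross <- purrr::imap_dfr(mols[-1], function(m, acc) {
    tibble(accession = acc,
           molecule = c("mol A", "mol B"),
           rmsd = c(kabsch_superpose(m[[1]], ref[[1]])$rmsd,
                    kabsch_superpose(m[[2]], ref[[2]])$rmsd))
  })
  trip <- landmarks$triplets[landmarks$triplets$name %in% c("front", "back"), ]
  portal <- purrr::imap_dfr(mols, function(m, acc) {
    purrr::imap_dfr(m, function(s, molname) {
      vals <- vapply(seq_len(nrow(trip)), function(k) {
        p <- function(r) {
          a <- select_atom(s, r)
          c(a$x, a$y, a$z)
        }
        angle_points(p(trip$a[k]), p(trip$b[k]), p(trip$c[k]))
      }, numeric(1))
      tibble(accession = acc, molecule = molname,
             portal = trip$name, angle = vals)
    })
  })
  means <- portal |>
    dplyr::group_by(.data$portal) |>
    dplyr::summarise(mean_angle = mean(.data$angle),
                     n_molecules = dplyr::n(), .groups = "drop")
  list(intra = intra, cross = cross, portal_angles = portal,
       portal_means = means)
}
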