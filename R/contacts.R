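#' Ligand / lipid contacts with protein residues
#'
#' A protein residue is in contact with a partner group (drug, lipid) when
#' its minimum heavy-atom to heavy-atom distance to any partner atom is at
#' or below the cutoff. The default cutoff of 3.0 Angstrom is the strict
#' convention used for drug-domain interaction counting; hydrogens are
#' excluded by default. Both choices are exposed because distance
#' conventions vary between studies.
#'
#' @param protein A `cadyn_structure` (its non-HETATM atoms are used), or a
#'   tibble of atom records.
#' @param ligand Tibble of partner atoms with `x`, `y`, `z` (optional
#'   `element`, `partner` group id).
#' @param cutoff Contact cutoff, Angstrom (> 0).
#' @param include_hydrogens Keep hydrogen atoms on both sides?
#' @param map Optional `cadyn_domain_map` used to label contact residues
#'   with their regions (TM helices etc.).
#' @param regions Region names used for labelling (default: TM1..TM12 when
#'   present in `map`).
#' @param frame Frame index recorded in the output (for bookkeeping when
#'   scanning trajectories).
#' @return Tibble of contact records: `frame`, `chain_id`,
#'   `residue_number`, `residue_name`, `partner`, `min_dist`, `regions`.
#' @export
find_contacts <- function(protein, ligand, cutoff = 3.0,
                          include_hydrogens = FALSE, map = NULL,
                          regions = NULL, frame = 1L) {
  if (cutoff <= 0) abort("cutoff must be > 0")
  het <- if ("het" %in% names(protein)) protein$het else
    rep(FALSE, nrow(protein))
  prot <- protein[!het, ]
  lig <- as_tibble(ligand)
  if (!include_hydrogens) {
    prot <- drop_hydrogens(prot)
    lig <- drop_hydrogens(lig)
  }
  if (nrow(prot) == 0) abort("empty protein atom set")
  if (nrow(lig) == 0) abort("empty ligand atom set")
  pm <- cbind(prot$x, prot$y, prot$z)
  lm <- cbind(lig$x, lig$y, lig$z)
  partner <- if ("partner" %in% names(lig)) lig$partner else
    rep("ligand", nrow(lig))
  ## all-pairs minimum distance per (residue, partner group)
  d2 <- outer(rowSums(pm^2), rowSums(lm^2), `+`) - 2 * pm %*% t(lm)
  d2[d2 < 0] <- 0
  res_key <- paste(prot$chain_id, prot$residue_number)
  recs <- list()
  for (grp in unique(partner)) {
    dmin <- sqrt(apply(d2[, partner == grp, drop = FALSE], 1, min))
    best <- tapply(dmin, res_key, min)
    first <- !duplicated(res_key)
    info <- prot[first, c("chain_id", "residue_number", "residue_name")]
    info$min_dist <- as.numeric(best[match(res_key[first], names(best))])
    info <- info[info$min_dist <= cutoff, ]
    if (nrow(info)) {
      info$partner <- grp
      recs[[length(recs) + 1]] <- info
    }
  }
  out <- if (length(recs)) dplyr::bind_rows(recs) else
    tibble(chain_id = character(), residue_number = integer(),
           residue_name = character(), min_dist = numeric(),
           partner = character())
  out$frame <- as.integer(frame)
  if (!is.null(map)) {
    regions <- regions %||% intersect(paste0("TM", 1:12),
                                      unique(map$region))
    out$regions <- if (nrow(out)) {
      region_labels(map, out$residue_number, regions = regions)
    } else character()
  } else {
    out$regions <- rep(NA_character_, nrow(out))
  }
  out[, c("frame", "chain_id", "residue_number", "residue_name", "partner",
          "min_dist", "regions")]
}

drop_hydrogens <- function(df) {
  el <- if ("element" %in% names(df)) df$element else
    rep(NA_character_, nrow(df))
  nm <- if ("atom_name" %in% names(df)) df$atom_name else
    rep("C", nrow(df))
  fill <- is.na(el) | !nzchar(el)
  el[fill] <- guess_element(nm[fill])
  df[toupper(el) != "H", ]
}

#' Scan contacts over trajectory frames
#'
#' Runs [find_contacts()] on each requested frame of a trajectory whose
#' roster mixes protein and partner atoms (partner = HETATM rows of
#' `partner_chain`, or an explicit roster predicate).
#'
#' @param traj A `cadyn_trajectory` whose roster carries `residue_name`.
#' @param partner_chain Chain id(s) holding the partner (ligand/lipid)
#'   atoms.
#' @inheritParams find_contacts
#' @param frames Frame indices to scan (default all).
#' @return Contact records across frames (see [find_contacts()]).
#' @export
contact_timeseries <- function(traj, partner_chain, cutoff = 3.0,
                               include_hydrogens = FALSE, map = NULL,
                               regions = NULL, frames = NULL) {
  frames <- frames %||% seq_len(n_frames(traj))
  is_partner <- traj$roster$chain_id %in% partner_chain
  if (!any(is_partner)) abort("no roster atoms on the partner chain")
  if (all(is_partner)) abort("no protein atoms left after partner split")
  dplyr::bind_rows(lapply(frames, function(i) {
    s <- frame_structure(traj, i)
    lig <- s[is_partner, ]
    lig$partner <- lig$chain_id
    find_contacts(s[!is_partner, ], lig, cutoff = cutoff,
                  include_hydrogens = include_hydrogens, map = map,
                  regions = regions, frame = i)
  }))
}

#' Aggregate contact records per transmembrane helix
#'
#' Counts the distinct contact residues falling in each TM region over a
#' window of records; residues outside every TM region are pooled under
#' `"other"`. Per-residue contact frequency (fraction of scanned frames in
#' contact) is returned alongside.
#'
#' @param records Contact records from [find_contacts()] /
#'   [contact_timeseries()].
#' @param map A `cadyn_domain_map` defining the TM regions.
#' @param regions TM region names (default TM1..TM12 present in `map`).
#' @param n_frames Number of frames scanned (for the frequency table);
#'   default = number of distinct frames in `records`.
#' @return A `cadyn_contact_profile` list with tibbles `per_tm` (`region`,
#'   `n_residues`) and `per_residue` (`chain_id`, `residue_number`,
#'   `residue_name`, `n_frames_in_contact`, `frequency`).
#' @export
aggregate_per_tm <- function(records, map, regions = NULL, n_frames = NULL) {
  regions <- regions %||% intersect(paste0("TM", 1:12), unique(map$region))
  nf <- n_frames %||% max(1L, length(unique(records$frame)))
  if (nrow(records) == 0) {
    per_tm <- tibble(region = c(regions, "other"), n_residues = 0L)
    per_res <- tibble(chain_id = character(), residue_number = integer(),
                      residue_name = character(),
                      n_frames_in_contact = integer(), frequency = numeric())
  } else {
    uniq <- records |>
      dplyr::distinct(.data$chain_id, .data$residue_number,
                      .data$residue_name)
    lab <- region_labels(map, uniq$residue_number, regions = regions)
    counts <- vapply(regions, function(rg) {
      sum(vapply(strsplit(lab, ","), function(v) rg %in% v, logical(1)))
    }, integer(1))
    per_tm <- tibble(region = c(regions, "other"),
                     n_residues = unname(c(counts, sum(lab == "other"))))
    per_res <- records |>
      dplyr::distinct(.data$frame, .data$chain_id, .data$residue_number,
                      .data$residue_name) |>
      dplyr::count(.data$chain_id, .data$residue_number, .data$residue_name,
                   name = "n_frames_in_contact") |>
      dplyr::mutate(frequency = .data$n_frames_in_contact / nf)
  }
  structure(list(per_tm = per_tm, per_residue = per_res, n_frames = nf),
            class = "cadyn_contact_profile")
}

#' @export
print.cadyn_contact_profile <- function(x, ...) {
  cat(sprintf("<cadyn_contact_profile> over %d frame(s)\n", x$n_frames))
  print(x$per_tm)
  invisible(x)
}

#' Census of aromatic residues in a region
#'
#' Counts PHE/TYR/TRP/HIS residues in a region or residue range —
#' the composition statistic behind portal and binding-cavity aromaticity
#' comparisons (e.g. the phenylalanine-rich front portal of
#' P-glycoprotein).
#'
#' @param structure A `cadyn_structure`.
#' @param residues Residue numbers to scan, or `NULL` with `region`/`map`.
#' @param region,map Optional region name resolved through a domain map.
#' @param chain Optional chain filter.
#' @return Tibble with `residue_name`, `n`, `residues` (comma-joined
#'   residue numbers). Regions without aromatics give zero counts.
#' @export
aromatic_census <- function(structure, residues = NULL, region = NULL,
                            map = NULL, chain = NULL) {
  if (is.null(residues)) {
    if (is.null(region) || is.null(map)) {
      abort("pass `residues`, or `region` together with `map`")
    }
    residues <- region_residues(map, region, chain)
  }
  aromatics <- c("PHE", "TYR", "TRP", "HIS")
  s <- structure[!structure$het &
                   structure$residue_number %in% residues, ]
  if (!is.null(chain)) s <- s[s$chain_id %in% chain, ]
  s <- s[!duplicated(paste(s$chain_id, s$residue_number)), ]
  purrr::map_dfr(aromatics, function(aa) {
    hit <- sort(unique(s$residue_number[s$residue_name == aa]))
    tibble(residue_name = aa, n = length(hit),
           residues = paste(hit, collapse = ","))
  })
}
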