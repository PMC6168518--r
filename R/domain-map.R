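#' Domain maps: named residue-range regions
#'
#' A domain map assigns names (TM1..TM12, NBD1, NBD2, half1, half2, cavity,
#' portals, ...) to residue-number ranges, optionally per chain. It is a
#' tibble with columns `region`, `chain_id` (`NA` = any chain), `start`,
#' `end`; a region may span several rows and a residue may belong to several
#' regions. The two pseudo-symmetric halves default to residues 40-626
#' (half1) and 691-1271 (half2), the halves of mouse P-glycoprotein.
#'
#' `load_domain_map()` parses a key/value text config, one region per line:
#' `region: [chain:]start-end[, [chain:]start-end ...]`. Omitted `half1` /
#' `half2` are filled with the defaults above. A region name given on two
#' different lines is a config error.
#'
#' @param config Path to a config file, its text content, or `""`/`NULL` for
#'   defaults only.
#' @return A `cadyn_domain_map` tibble.
#' @export
load_domain_map <- function(config = NULL) {
  rows <- list()
  if (!is.null(config) && any(nzchar(config))) {
    if (length(config) == 1 && !grepl("\n", config) && file.exists(config)) {
      lines <- readLines(config, warn = FALSE)
    } else {
      lines <- unlist(strsplit(config, "\n", fixed = TRUE))
    }
    lines <- trimws(lines)
    lines <- lines[nzchar(lines) & !grepl("^#", lines)]
    seen <- character()
    for (ln in lines) {
      m <- regmatches(ln, regexec("^([^:]+):(.+)$", ln))[[1]]
      if (length(m) != 3) abort(paste0("malformed domain-map line: ", ln))
      region <- trimws(m[2])
      if (region %in% seen) {
        abort(paste0("region '", region, "' defined twice"))
      }
      seen <- c(seen, region)
      for (part in trimws(strsplit(m[3], ",", fixed = TRUE)[[1]])) {
        pm <- regmatches(part, regexec(
          "^(?:([A-Za-z0-9]+):)?(-?[0-9]+)\\s*[-–]\\s*(-?[0-9]+)$",
          part))[[1]]
        if (length(pm) != 4) {
          abort(paste0("malformed range '", part, "' in region ", region))
        }
        start <- as.integer(pm[3]); end <- as.integer(pm[4])
        if (start > end) {
          abort(sprintf("malformed range %d-%d in region %s (start > end)",
                        start, end, region))
        }
        rows[[length(rows) + 1]] <- tibble(
          region = region,
          chain_id = if (nzchar(pm[2])) pm[2] else NA_character_,
          start = start, end = end)
      }
    }
  }
  map <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble(region = character(), chain_id = character(),
           start = integer(), end = integer())
  if (!"half1" %in% map$region) {
    map <- dplyr::bind_rows(map, tibble(region = "half1",
                                        chain_id = NA_character_,
                                        start = 40L, end = 626L))
  }
  if (!"half2" %in% map$region) {
    map <- dplyr::bind_rows(map, tibble(region = "half2",
                                        chain_id = NA_character_,
                                        start = 691L, end = 1271L))
  }
  class(map) <- c("cadyn_domain_map", class(tibble()))
  map
}

#' Default P-glycoprotein domain map
#'
#' Residue ranges for the twelve transmembrane helices, the two
#' nucleotide-binding domains and the two bilayer portals of mouse
#' P-glycoprotein (author numbering). The half1/half2 boundaries (40-626,
#' 691-1271) are the published halves; the TM/NBD boundaries are this
#' package's working conventions — approximate helix limits chosen so that
#' the standard landmark residues fall in their textbook helices — and are
#' meant to be overridden from a config file when exact boundaries matter.
#'
#' @return A `cadyn_domain_map` tibble.
#' @export
pgp_domain_map <- function() {
  load_domain_map(paste(
    "TM1: 45-72",     "TM2: 113-137",   "TM3: 187-209",  "TM4: 212-238",
    "TM5: 291-315",   "TM6: 327-352",   "TM7: 706-730",  "TM8: 751-775",
    "TM9: 828-852",   "TM10: 854-878",  "TM11: 931-955", "TM12: 970-994",
    "NBD1: 392-626",  "NBD2: 1027-1271",
    "front_portal: 212-238, 327-352",
    "back_portal: 854-878, 970-994",
    "cavity: 327-352, 970-994, 45-72, 706-730, 291-315, 931-955",
    sep = "\n"))
}

#' Residue numbers belonging to a region
#'
#' @param map A `cadyn_domain_map`.
#' @param region Region name.
#' @param chain Optional chain; rows bound to other chains are skipped.
#' @return Integer vector of residue numbers; errors on unknown region.
#' @export
region_residues <- function(map, region, chain = NULL) {
  rows <- map[map$region == region, ]
  if (nrow(rows) == 0) abort(paste0("region '", region, "' not in domain map"))
  if (!is.null(chain)) rows <- rows[is.na(rows$chain_id) |
                                      rows$chain_id == chain, ]
  sort(unique(unlist(Map(seq.int, rows$start, rows$end))))
}

#' Label residues with the regions that contain them
#'
#' @inheritParams region_residues
#' @param residue_numbers Integer vector.
#' @param regions Region names to test (default: all in the map).
#' @return Character vector, comma-joined region labels (`"other"` when a
#'   residue falls in none).
#' @export
region_labels <- function(map, residue_numbers, regions = NULL,
                          chain = NULL) {
  regions <- regions %||% unique(map$region)
  hits <- lapply(regions, function(rg) {
    residue_numbers %in% region_residues(map, rg, chain = chain)
  })
  vapply(seq_along(residue_numbers), function(i) {
    inside <- regions[vapply(hits, `[[`, logical(1), i)]
    if (length(inside)) paste(inside, collapse = ",") else "other"
  }, character(1))
}
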