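#' The standard landmark monitors for P-glycoprotein
#'
#' Conformational change of the transporter is monitored with named Ca
#' landmark residue pairs (distances) and triplets (interior angles):
#'
#' * seven pairs across the two pseudo-symmetric halves — the extracellular
#'   gates `A79-T736` (ECL1-ECL3), `G207-G850` (TM3-TM9), `G325-E968`
#'   (ECL2-ECL4); the cavity pairs `F71-F728` and `Q343-Q986`; and the
#'   ATP-site pairs `K429-S1173` (site 1) and `K1072-S528` (site 2), whose
#'   residues come from the Walker A and LSGGQ motifs that sandwich ATP;
#' * four triplets — the NBD alignment angles `K429-G1175-L1182` (site1)
#'   and `K1072-G530-L537` (site2), which approach 180 degrees in a
#'   canonical ATP-sandwich dimer, and the bilayer-portal opening angles
#'   `G226-L215-S345` (front, TM4/TM6) and `V869-L858-S988` (back,
#'   TM10/TM12).
#'
#' @return A `cadyn_landmarks` list with tibbles `pairs` (`name`, `label`,
#'   `a`, `b`) and `triplets` (`name`, `label`, `a`, `b`, `c`); entries are
#'   residue numbers, the Ca atom implied.
#' @export
default_landmarks <- function() {
  new_landmarks(
    pairs = tibble(
      name  = c("ecl1_ecl3", "tm3_tm9", "ecl2_ecl4", "f71_f728",
                "q343_q986", "site1_dist", "site2_dist"),
      label = c("A79-T736", "G207-G850", "G325-E968", "F71-F728",
                "Q343-Q986", "K429-S1173", "K1072-S528"),
      a = c(79L, 207L, 325L, 71L, 343L, 429L, 1072L),
      b = c(736L, 850L, 968L, 728L, 986L, 1173L, 528L)),
    triplets = tibble(
      name  = c("site1", "site2", "front", "back"),
      label = c("K429-G1175-L1182", "K1072-G530-L537",
                "G226-L215-S345", "V869-L858-S988"),
      a = c(429L, 1072L, 226L, 869L),
      b = c(1175L, 530L, 215L, 858L),
      c = c(1182L, 537L, 345L, 988L)))
}

#' Build a landmark set
#' @param pairs Tibble with `name`, `a`, `b` (residue numbers; optional
#'   `label`).
#' @param triplets Tibble with `name`, `a`, `b`, `c` (optional `label`).
#' @return A `cadyn_landmarks` object.
#' @export
new_landmarks <- function(pairs = NULL, triplets = NULL) {
  empty_p <- tibble(name = character(), label = character(),
                    a = integer(), b = integer())
  empty_t <- tibble(name = character(), label = character(),
                    a = integer(), b = integer(), c = integer())
  pairs <- if (is.null(pairs)) empty_p else as_tibble(pairs)
  triplets <- if (is.null(triplets)) empty_t else as_tibble(triplets)
  if (!"label" %in% names(pairs)) pairs$label <- pairs$name
  if (!"label" %in% names(triplets)) triplets$label <- triplets$name
  if (any(pairs$a == pairs$b)) abort("a landmark pair must join two distinct residues")
  if (any(triplets$b == triplets$a | triplets$b == triplets$c)) {
    abort("a triplet vertex must differ from both arms")
  }
  if (anyDuplicated(c(pairs$name, triplets$name))) {
    abort("landmark names must be unique")
  }
  structure(list(pairs = pairs, triplets = triplets),
            class = "cadyn_landmarks")
}

#' @export
print.cadyn_landmarks <- function(x, ...) {
  cat(sprintf("<cadyn_landmarks> %d pairs, %d triplets\n",
              nrow(x$pairs), nrow(x$triplets)))
  invisible(x)
}

#' Look up one landmark by name
#' @param set A `cadyn_landmarks`.
#' @param name Landmark name.
#' @return One-row tibble (pair or triplet); errors when absent.
#' @export
landmark <- function(set, name) {
  if (name %in% set$pairs$name) return(set$pairs[set$pairs$name == name, ])
  if (name %in% set$triplets$name) {
    return(set$triplets[set$triplets$name == name, ])
  }
  abort(paste0("landmark '", name, "' not found"))
}

#' Evaluate landmarks over a trajectory
#'
#' @param traj A `cadyn_trajectory` (a `cadyn_structure` is promoted to one
#'   frame).
#' @param landmarks A `cadyn_landmarks` (default [default_landmarks()]).
#' @param chain Chain override for two-molecule rosters; by default each
#'   residue must resolve unambiguously.
#' @return Tidy tibble with `frame`, `time_ps`, `name`, `kind`
#'   (`"distance"`/`"angle"`), `value` (Angstrom / degrees).
#' @export
landmark_timeseries <- function(traj, landmarks = default_landmarks(),
                                chain = NULL) {
  if (inherits(traj, "cadyn_structure")) traj <- as_trajectory(traj)
  res <- function(r) resolve_residue(traj$roster, r, chain = chain)
  f <- n_frames(traj)
  time_ps <- (seq_len(f) - 1) * traj$frame_interval_ps
  out <- list()
  for (k in seq_len(nrow(landmarks$pairs))) {
    p <- landmarks$pairs[k, ]
    ia <- res(p$a); ib <- res(p$b)
    d <- sqrt(rowSums(matrix(traj$coords[, ia, ] - traj$coords[, ib, ],
                             ncol = 3)^2))
    out[[length(out) + 1]] <- tibble(frame = seq_len(f), time_ps = time_ps,
                                     name = p$name, kind = "distance",
                                     value = d)
  }
  for (k in seq_len(nrow(landmarks$triplets))) {
    tr <- landmarks$triplets[k, ]
    ia <- res(tr$a); ib <- res(tr$b); ic <- res(tr$c)
    v <- vapply(seq_len(f), function(i) {
      angle_points(traj$coords[i, ia, ], traj$coords[i, ib, ],
                   traj$coords[i, ic, ])
    }, numeric(1))
    out[[length(out) + 1]] <- tibble(frame = seq_len(f), time_ps = time_ps,
                                     name = tr$name, kind = "angle",
                                     value = v)
  }
  dplyr::bind_rows(out)
}

#' Equilibrium-window summary of a metric series
#'
#' Means and standard deviations over a frame window, by default the final
#' 20% of frames — the equilibrium-ensemble convention (2000 frames of a
#' 10 000-frame, 10 ps cadence run, i.e. the last 20 ns of 100 ns).
#'
#' @param series Tidy tibble from [landmark_timeseries()] (or any tibble
#'   with `frame`, `name`, `value`), or a plain numeric vector.
#' @inheritParams window_frames
#' @return Tibble with `name`, `window_start`, `window_end`, `n`, `mean`,
#'   `sd`.
#' @export
equilibrium_summary <- function(series, window = NULL, fraction = 0.2) {
  if (is.numeric(series) && is.null(dim(series))) {
    series <- tibble(frame = seq_along(series), name = "series",
                     value = series)
  }
  frames <- sort(unique(series$frame))
  win <- window_frames(length(frames), window, fraction)
  keep <- series$frame %in% frames[win]
  if (!any(keep)) abort("empty equilibrium window")
  series[keep, ] |>
    dplyr::group_by(.data$name) |>
    dplyr::summarise(window_start = frames[min(win)],
                     window_end = frames[max(win)],
                     n = dplyr::n(), mean = mean(.data$value),
                     sd = if (dplyr::n() > 1) sd(.data$value) else 0,
                     .groups = "drop")
}

#' Two-sample t-test between groups of per-run equilibrium means
#'
#' Compares two simulation groups (e.g. apo vs drug-occupied) on a landmark
#' metric, taking one observation per run — the run's equilibrium-window
#' mean — so frames within a run are never treated as independent samples.
#' Welch's unequal-variance two-tailed test by default; set
#' `var_equal = TRUE` for Student's pooled test. Differences are flagged
#' significant at p < 0.05.
#'
#' @param group_a,group_b Numeric vectors of per-run means (each `n >= 2`).
#' @param var_equal Use the pooled-variance (Student) test instead of Welch.
#' @param alpha Significance level for the `significant` flag.
#' @return A `cadyn_ttest` one-row tibble: `mean_a`, `mean_b`, `estimate`
#'   (mean_a - mean_b), `statistic`, `df`, `p_value`, `significant`,
#'   `method`.
#' @export
welch_t <- function(group_a, group_b, var_equal = FALSE, alpha = 0.05) {
  if (length(group_a) < 2 || length(group_b) < 2) {
    abort("each group needs at least 2 runs")
  }
  if (sd(group_a) == 0 && sd(group_b) == 0) {
    abort("degenerate input: both groups have zero variance")
  }
  tt <- t.test(group_a, group_b, var.equal = var_equal,
               alternative = "two.sided")
  out <- tibble(
    mean_a = mean(group_a), mean_b = mean(group_b),
    estimate = mean(group_a) - mean(group_b),
    statistic = unname(tt$statistic), df = unname(tt$parameter),
    p_value = tt$p.value, significant = tt$p.value < alpha,
    method = if (var_equal) "student" else "welch")
  class(out) <- c("cadyn_ttest", class(tibble()))
  out
}
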