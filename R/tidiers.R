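#' Broom-style tidiers
#'
#' `tidy()` returns per-component tibbles; `glance()` one-row model
#' summaries.
#'
#' @param x A fitted cadyn object.
#' @param ... Unused.
#' @name cadyn-tidiers
NULL

#' @rdname cadyn-tidiers
#' @export
tidy.cadyn_superposition <- function(x, ...) {
  tibble(component = c(paste0("rotation[", rep(1:3, each = 3), ",",
                              rep(1:3, 3), "]"),
                       paste0("translation[", 1:3, "]")),
         value = c(as.vector(t(x$rotation)), x$translation))
}

#' @rdname cadyn-tidiers
#' @export
glance.cadyn_superposition <- function(x, ...) {
  tibble(rmsd = x$rmsd, n_atoms = x$n_atoms)
}

#' @rdname cadyn-tidiers
#' @export
tidy.cadyn_anm <- function(x, ...) {
  x <- anm_modes(x)
  zero <- zero_mode_mask(x)
  tibble(mode = seq_along(x$eigenvalues), eigenvalue = x$eigenvalues,
         zero_mode = zero,
         frequency = sqrt(pmax(x$eigenvalues, 0)))
}

#' @rdname cadyn-tidiers
#' @export
glance.cadyn_anm <- function(x, ...) {
  n_zero <- if (is.null(x$eigenvalues)) NA_integer_ else n_zero_modes(x)
  tibble(n_nodes = x$n_nodes, n_modes = 3 * x$n_nodes,
         n_zero_modes = n_zero, cutoff = x$cutoff, gamma = x$gamma,
         connected = x$connected)
}

#' @rdname cadyn-tidiers
#' @export
tidy.cadyn_dccm <- function(x, ...) {
  n <- nrow(x)
  tibble(i = rep(seq_len(n), n), j = rep(seq_len(n), each = n),
         correlation = as.vector(unclass(x)))
}

#' @rdname cadyn-tidiers
#' @export
glance.cadyn_dccm <- function(x, ...) {
  off <- x[upper.tri(x)]
  tibble(n_atoms = nrow(x), mean_offdiag = mean(off),
         min = min(off), max = max(off))
}
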