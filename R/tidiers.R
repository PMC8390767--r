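#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a single-voxel fit
#'
#' @param x An `mp_fit` from [refine()] / [fit_train()].
#' @param ... Unused.
#' @return Tibble with one row per parameter (`term`, `estimate`),
#'   including the derived `T1`, `T2` (ms), `PD` and `B0_hz`.
#' @export
tidy.mp_fit <- function(x, ...) {
  th <- x$theta
  tr <- x$tr_ip
  tibble::tibble(
    term = c(names(th), "T1", "T2", "PD", "B0_hz"),
    estimate = c(unname(th),
                 -tr / log(th[["E1"]]), -tr / log(th[["E2"]]),
                 sqrt(th[["ReS0"]]^2 + th[["ImS0"]]^2),
                 th[["beta"]] / (2 * pi * tr * 1e-3))
  )
}

#' @rdname tidy.mp_fit
#' @export
glance.mp_fit <- function(x, ...) {
  tibble::tibble(cost = x$cost, converged = x$converged,
                 winning_start = x$winning_start, n_echo = x$n_echo)
}

#' Tidy a voxelwise map fit
#'
#' @param x An `mp_mapfit` from [fit_dataset()].
#' @param ... Unused.
#' @return [tidy()] returns the assembled parameter maps (one row per
#'   voxel, see [assemble_maps()]); [glance()] a one-row fit summary.
#' @export
tidy.mp_mapfit <- function(x, ...) {
  assemble_maps(x)
}

#' @rdname tidy.mp_mapfit
#' @export
glance.mp_mapfit <- function(x, ...) {
  tibble::tibble(
    n_voxels = nrow(x),
    n_converged = sum(x$converged, na.rm = TRUE),
    median_cost = stats::median(x$cost, na.rm = TRUE)
  )
}

#' Long-format echoes of a dataset
#'
#' @param x An `mp_dataset` from [simulate_dataset()].
#' @param ... Unused.
#' @return Tibble with `x`, `y`, `vial`, `echo`, `re`, `im`.
#' @export
tidy.mp_dataset <- function(x, ...) {
  ph <- x$phantom
  n_echo <- nrow(x$echoes)
  tibble::tibble(
    x = rep(ph$x, each = n_echo),
    y = rep(ph$y, each = n_echo),
    vial = rep(ph$vial, each = n_echo),
    echo = rep(seq_len(n_echo), times = ncol(x$echoes)),
    re = as.vector(Re(x$echoes)),
    im = as.vector(Im(x$echoes))
  )
}
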