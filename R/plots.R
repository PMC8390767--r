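#' Plot an eigenvalue map on the complex plane
#'
#' The conjugate-pair eigenvalue `rho e^{i phi}` (and its mirror) and the
#' real eigenvalue `eta` for every species of the grid, coloured by
#' off-resonance.
#'
#' @param emap An [eigenvalue_map()] result.
#' @return A ggplot object.
#' @export
plot_eigenvalue_map <- function(emap) {
  em <- dplyr::filter(emap, .data$ok)
  pts <- dplyr::bind_rows(
    dplyr::mutate(em, re = .data$rho * cos(.data$phi),
                  imv = .data$rho * sin(.data$phi), branch = "pair"),
    dplyr::mutate(em, re = .data$rho * cos(.data$phi),
                  imv = -.data$rho * sin(.data$phi), branch = "pair"),
    dplyr::mutate(em, re = .data$eta, imv = 0, branch = "real")
  )
  ggplot2::ggplot(pts, ggplot2::aes(.data$re, .data$imv,
                                    colour = .data$beta,
                                    shape = .data$branch)) +
    ggplot2::geom_point(alpha = 0.7, size = 1) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "Re", y = "Im", colour = "beta (rad)",
                  title = "Propagator eigenvalues over the species grid") +
    ggplot2::theme_minimal()
}

#' Raster plot of a parameter map
#'
#' @param maps Voxel table with `x`, `y` and the chosen field (e.g. from
#'   [assemble_maps()] or an `mp_phantom`).
#' @param field Column to display (string).
#' @return A ggplot object.
#' @export
plot_map <- function(maps, field = "T1") {
  ggplot2::ggplot(maps, ggplot2::aes(.data$x, .data$y,
                                     fill = .data[[field]])) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c(na.value = "grey20") +
    ggplot2::labs(title = field) +
    ggplot2::theme_minimal()
}

#' Plot an echo train and (optionally) its fitted model
#'
#' @param S Complex echo train.
#' @param fit Optional `mp_fit`; when given, the fitted model train is
#'   overlaid.
#' @param block,n_blocks Acquisition geometry used for the overlay.
#' @return A ggplot object showing real and imaginary channels.
#' @export
plot_echo_train <- function(S, fit = NULL, block = scheme_block("mp"),
                            n_blocks = 25) {
  d <- tibble::tibble(echo = seq_along(S),
                      re = Re(S), im = Im(S))
  d <- tidyr::pivot_longer(d, c("re", "im"), names_to = "channel",
                           values_to = "signal")
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$echo, .data$signal,
                                       colour = .data$channel)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "echo index", y = "signal (a.u.)") +
    ggplot2::theme_minimal()
  if (!is.null(fit) && isTRUE(fit$converged)) {
    m <- forward_model(fit$theta, block, n_blocks)
    dm <- tibble::tibble(echo = seq_along(m), re = Re(m), im = Im(m))
    dm <- tidyr::pivot_longer(dm, c("re", "im"), names_to = "channel",
                              values_to = "signal")
    p <- p + ggplot2::geom_line(data = dm, linewidth = 0.4)
  }
  p
}

#' Autoplot methods
#'
#' `autoplot()` for the package's main result types: a dataset shows the
#' magnitude of the first echo; a map fit shows the T1 map.
#'
#' @param object An `mp_dataset` or `mp_mapfit`.
#' @param field Map column for `mp_mapfit` (default `"T1"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mp_dataset <- function(object, ...) {
  ph <- object$phantom
  d <- dplyr::mutate(tibble::as_tibble(ph),
                     mag = Mod(object$echoes[1, ]))
  plot_map(d, "mag")
}

#' @rdname autoplot.mp_dataset
#' @export
autoplot.mp_mapfit <- function(object, field = "T1", ...) {
  plot_map(assemble_maps(object), field)
}
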