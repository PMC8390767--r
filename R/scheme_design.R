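#' Default species grid for eigenvalue maps
#'
#' A `(T2, beta)` parameter grid at fixed `T1`, mirroring the grids used to
#' inspect candidate schemes: `T2` log-spaced over `[20, 300]` ms (16
#' points, a package default, not a reported value), `beta` uniform over
#' `[0, 2 pi)` (32 points), `T1 = 878` ms.
#'
#' @param T2_values T2 grid, ms (sorted).
#' @param beta_values Off-resonance phases per inter-pulse period, radians.
#' @param T1 Fixed longitudinal relaxation time, ms.
#' @return Tibble with columns `T2`, `beta` (full factorial) and grid
#'   indices `i_T2`, `i_beta`; `T1` attached as an attribute.
#' @export
species_grid <- function(T2_values = exp(seq(log(20), log(300), length.out = 16)),
                         beta_values = seq(0, 2 * pi, length.out = 33)[-33],
                         T1 = 878) {
  stopifnot(length(T2_values) >= 1, length(beta_values) >= 1,
            !is.unsorted(T2_values), !is.unsorted(beta_values))
  g <- tidyr::expand_grid(
    i_T2 = seq_along(T2_values),
    i_beta = seq_along(beta_values)
  )
  g <- dplyr::mutate(g, T2 = T2_values[.data$i_T2],
                     beta = beta_values[.data$i_beta])
  attr(g, "T1") <- T1
  g
}

#' Eigenvalue map of a scheme over a species grid
#'
#' Evaluates the eigen-parametrization `(rho, phi, eta)` of the block
#' propagator for every `(T2, beta)` species on a grid: the propagator
#' viewed as a mapping from parameter space to the complex-eigenvalue
#' space. Per-species failures are recorded, not propagated.
#'
#' @param block A [block_spec()] (e.g. from [scheme_block()]); flip angles
#'   are taken as nominal (`B1 = 1`).
#' @param grid A [species_grid()].
#' @param T1 Longitudinal relaxation time, ms; defaults to the grid's.
#' @return Tibble: grid columns plus `rho`, `phi`, `eta`, `oscillatory`,
#'   `ho` (`rho^2 eta`), `ok`.
#' @export
eigenvalue_map <- function(block, grid = species_grid(), T1 = NULL) {
  stopifnot(inherits(block, "block_spec"))
  T1 <- T1 %||% attr(grid, "T1") %||% 878
  if (nrow(grid) == 0L) {
    return(dplyr::mutate(grid, rho = numeric(0), phi = numeric(0),
                         eta = numeric(0), oscillatory = logical(0),
                         ok = logical(0), ho = numeric(0)))
  }
  res <- purrr::pmap(list(grid$T2, grid$beta), function(T2, beta) {
    et <- tryCatch({
      vox <- voxel_params(T1 = T1, T2 = min(T2, T1), PD = 1, beta = beta)
      eigen_parametrize(compose_block(block, vox)$matrix)
    }, error = function(e) NULL)
    if (is.null(et) || is.na(et$oscillatory)) {
      tibble::tibble(rho = NA_real_, phi = NA_real_, eta = NA_real_,
                     oscillatory = NA, ok = FALSE)
    } else {
      tibble::tibble(rho = et$rho, phi = et$phi, eta = et$eta,
                     oscillatory = et$oscillatory, ok = TRUE)
    }
  })
  out <- dplyr::bind_cols(grid, dplyr::bind_rows(res))
  dplyr::mutate(out, ho = .data$rho^2 * .data$eta)
}

#' Topology-preservation diagnostic of an eigenvalue map
#'
#' A usable scheme must map distinct `(T2, beta)` species to distinct
#' eigenvalue-pair points (single-valuedness) and keep grid neighbours
#' close (proximity). The check reports
#' \describe{
#'   \item{collisions}{pairs of species whose eigenvalue-plane distance
#'     `|rho e^{i phi} - rho' e^{i phi'}|` is below `collision_tol` while
#'     their grid-index (Chebyshev) distance exceeds 2 steps;}
#'   \item{neighbour violations}{grid-adjacent species mapped further
#'     apart than `jump_factor` times the median adjacent spacing.}
#' }
#'
#' Species pairs related by `beta -> -beta` (mod `2 pi`) at equal `T2` are
#' never counted: the eigenvalues of a real propagator come in conjugate
#' pairs, so the `(rho, |phi|)` plane folds that mirror symmetry by
#' construction for every scheme, while the signal phase still separates
#' the two species.
#'
#' @param emap An [eigenvalue_map()] result.
#' @param collision_tol Eigenvalue-plane distance counted as a collision.
#' @param jump_factor Multiple of the median neighbour spacing counted as
#'   a proximity violation.
#' @return List of class `topology_report`: `pass`, `collisions` (tibble),
#'   `neighbour_violations` (tibble), `median_spacing`.
#' @export
topology_check <- function(emap, collision_tol = 1e-6, jump_factor = 20) {
  em <- dplyr::filter(emap, .data$ok)
  z <- complex(modulus = em$rho, argument = em$phi)
  n <- length(z)
  collisions <- tibble::tibble(i = integer(), j = integer(),
                               eig_dist = numeric(), grid_dist = numeric())
  if (n >= 2) {
    pairs <- utils::combn(n, 2)
    dz <- Mod(z[pairs[1, ]] - z[pairs[2, ]])
    gd <- pmax(abs(em$i_T2[pairs[1, ]] - em$i_T2[pairs[2, ]]),
               abs(em$i_beta[pairs[1, ]] - em$i_beta[pairs[2, ]]))
    mirror <- abs((em$beta[pairs[1, ]] + em$beta[pairs[2, ]]) %% (2 * pi)) <
      1e-9 & em$i_T2[pairs[1, ]] == em$i_T2[pairs[2, ]]
    hit <- which(dz < collision_tol & gd > 2 & !mirror)
    collisions <- tibble::tibble(
      i = pairs[1, hit], j = pairs[2, hit],
      eig_dist = dz[hit], grid_dist = gd[hit]
    )
  }
  # neighbour spacing along both grid directions (beta wraps around)
  nb <- dplyr::cross_join(em, em, suffix = c("", ".nb"))
  n_beta <- max(em$i_beta)
  nb <- dplyr::filter(
    nb,
    (abs(.data$i_T2 - .data$i_T2.nb) == 1L & .data$i_beta == .data$i_beta.nb) |
      (.data$i_T2 == .data$i_T2.nb &
         (abs(.data$i_beta - .data$i_beta.nb) == 1L |
            abs(.data$i_beta - .data$i_beta.nb) == n_beta - 1L))
  )
  nb <- dplyr::mutate(
    nb,
    spacing = Mod(complex(modulus = .data$rho, argument = .data$phi) -
                    complex(modulus = .data$rho.nb, argument = .data$phi.nb))
  )
  med <- stats::median(nb$spacing)
  viol <- dplyr::filter(nb, .data$spacing > jump_factor * med)
  viol <- dplyr::select(viol, dplyr::all_of(c("i_T2", "i_beta", "spacing")))
  structure(
    list(pass = nrow(collisions) == 0L && nrow(viol) == 0L,
         collisions = collisions, neighbour_violations = viol,
         median_spacing = med),
    class = "topology_report"
  )
}

#' @export
print.topology_report <- function(x, ...) {
  cat("<topology_report> ", if (x$pass) "PASS" else "FAIL", "\n", sep = "")
  cat("  collisions:", nrow(x$collisions),
      " neighbour violations:", nrow(x$neighbour_violations), "\n")
  invisible(x)
}

#' Banding sensitivity of a scheme
#'
#' Spread of the per-block oscillation frequency `phi` and decay modulus
#' `rho` across off-resonance `beta`. A small `phi` spread means every
#' voxel oscillates at (nearly) the same frequency regardless of its local
#' field offset, so no banding waves can propagate across the image during
#' the transient.
#'
#' @param block A [block_spec()].
#' @param vox A [voxel_params()] giving `T1`, `T2` (its `beta` is ignored).
#' @param beta_grid Off-resonance phases, radians; at least 8 points
#'   covering `[0, 2 pi)` unless a single point is given.
#' @return One-row tibble: `phi_max_dev`, `phi_mad`, `rho_max_dev`,
#'   `rho_mad` (max/median absolute deviation from the median).
#' @export
banding_metric <- function(block, vox,
                           beta_grid = seq(0, 2 * pi, length.out = 65)[-65]) {
  if (length(beta_grid) > 1 &&
      (length(beta_grid) < 8 || diff(range(beta_grid)) < pi)) {
    stop("beta_grid must have >= 8 points covering [0, 2*pi)", call. = FALSE)
  }
  ev <- purrr::map(beta_grid, function(b) {
    v <- voxel_params(vox$T1, vox$T2, vox$PD, beta = b, B1 = vox$B1)
    eigen_parametrize(compose_block(block, v)$matrix)
  })
  phi <- vapply(ev, function(e) if (isTRUE(e$oscillatory)) e$phi else NA_real_,
                numeric(1))
  rho <- vapply(ev, `[[`, numeric(1), "rho")
  dev <- function(x) {
    x <- x[is.finite(x)]
    if (length(x) == 0) return(c(NA_real_, NA_real_))
    d <- abs(x - stats::median(x))
    c(max(d), stats::median(d))
  }
  dp <- dev(phi); dr <- dev(rho)
  tibble::tibble(phi_max_dev = dp[1], phi_mad = dp[2],
                 rho_max_dev = dr[1], rho_mad = dr[2])
}
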