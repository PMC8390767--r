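#' Fit configuration
#'
#' Bounds and multi-start settings of the voxelwise estimator: candidate
#' points are drawn uniformly in `E1 in [0.9, 1]`, `E2 in [0.3, 1]`,
#' `beta in [-pi, pi]`, `B1 in [0.5, 1.5]`; the bounded least-squares
#' refinement starts from the best `n_starts` of `n_candidates` screened
#' points. Note the `E1` lower bound censors `T1` below about
#' `-tr_ip / log(0.9)` (about 285 ms at a 30 ms inter-pulse period);
#' widen it for short-T1 applications.
#'
#' @param e1_bounds,e2_bounds,beta_bounds,b1_bounds Length-2 bounds.
#' @param n_candidates Screened candidate count.
#' @param n_starts Refined start count.
#' @param seed Seed for the candidate draw.
#' @param maxiter Maximum refinement iterations per start.
#' @return A `fit_config` list.
#' @export
fit_config <- function(e1_bounds = c(0.9, 1), e2_bounds = c(0.3, 1),
                       beta_bounds = c(-pi, pi), b1_bounds = c(0.5, 1.5),
                       n_candidates = 1000, n_starts = 5, seed = 1,
                       maxiter = 100) {
  stopifnot(e1_bounds[1] < e1_bounds[2], e2_bounds[1] < e2_bounds[2],
            beta_bounds[1] < beta_bounds[2], b1_bounds[1] < b1_bounds[2],
            n_candidates >= 1, n_starts >= 1, n_starts <= n_candidates)
  structure(list(e1_bounds = e1_bounds, e2_bounds = e2_bounds,
                 beta_bounds = beta_bounds, b1_bounds = b1_bounds,
                 n_candidates = n_candidates, n_starts = n_starts,
                 seed = seed, maxiter = maxiter),
            class = "fit_config")
}

#' Single-species forward signal model
#'
#' The echo train `S0 * u(E1, E2, beta, B1)` where `u` is the unit-scale
#' single-species simulation (hard pulses, thermal-equilibrium start) and
#' `theta = [Re S0, Im S0, E1, E2, beta, B1]`. `E1`/`E2` are per-interval
#' decay factors over the inter-pulse period (`E = exp(-tr_ip / T)`;
#' `E = 1` is the infinite-T limit and is handled exactly).
#'
#' @param theta Length-6 parameter vector.
#' @param block Equal-interval [block_spec()].
#' @param n_blocks Block repetitions.
#' @return Complex echo-train vector.
#' @export
forward_model <- function(theta, block, n_blocks = 25) {
  pt <- block_pulse_table(block)
  u <- sim_train_cpp(pt$flip, pt$phase, as.integer(n_blocks),
                     theta[3], theta[4], 1, theta[5], theta[6], c(0, 0, 1))
  complex(real = theta[1], imaginary = theta[2]) * as.vector(u)
}

# draw the candidate table (E1, E2, beta, B1) for the screening stage
draw_candidates <- function(config) {
  with_seed(config$seed, {
    n <- config$n_candidates
    cbind(
      E1 = stats::runif(n, config$e1_bounds[1], config$e1_bounds[2]),
      E2 = stats::runif(n, config$e2_bounds[1], config$e2_bounds[2]),
      beta = stats::runif(n, config$beta_bounds[1], config$beta_bounds[2]),
      B1 = stats::runif(n, config$b1_bounds[1], config$b1_bounds[2])
    )
  })
}

# closed-form linear least-squares S0 and residual cost against unit
# trains U (n_echo x n_cand): S0_c = <u_c, S> / ||u_c||^2
screen_against <- function(S, U, cand, n_starts) {
  ip <- as.vector(crossprod(Conj(U), S))       # <u_c, S>
  nrm2 <- colSums(Mod(U)^2)
  S0 <- ip / nrm2
  cost <- sum(Mod(S)^2) - Mod(ip)^2 / nrm2
  ord <- order(cost)[seq_len(n_starts)]
  tibble::tibble(
    rank = seq_along(ord),
    ReS0 = Re(S0[ord]), ImS0 = Im(S0[ord]),
    E1 = cand[ord, "E1"], E2 = cand[ord, "E2"],
    beta = cand[ord, "beta"], B1 = cand[ord, "B1"],
    cost = cost[ord]
  )
}

#' Candidate screening for the multi-start fit
#'
#' Draws `n_candidates` pseudo-random `(E1, E2, beta, B1)` points within
#' the configured bounds, solves the complex scale `S0` for each by linear
#' least squares against the unit-scale model train, and returns the
#' `n_starts` lowest-cost candidates.
#'
#' @param S Complex echo train.
#' @param block Equal-interval [block_spec()].
#' @param n_blocks Block repetitions.
#' @param config A [fit_config()].
#' @return Tibble of start points (`ReS0`, `ImS0`, `E1`, `E2`, `beta`,
#'   `B1`, `cost`), or `NULL` with a warning for an all-zero train.
#' @export
candidate_screen <- function(S, block, n_blocks = 25, config = fit_config()) {
  if (all(Mod(S) == 0)) {
    warning("empty voxel: all-zero echo train", call. = FALSE)
    return(NULL)
  }
  pt <- block_pulse_table(block)
  cand <- draw_candidates(config)
  U <- candidate_trains_cpp(cand, pt$flip, pt$phase, as.integer(n_blocks))
  screen_against(S, U, cand, config$n_starts)
}

#' Bounded least-squares refinement
#'
#' Refines each screened start by bounded Levenberg-Marquardt least
#' squares on the real/imaginary-stacked residual and returns the
#' lowest-cost converged result.
#'
#' @param S Complex echo train.
#' @param starts Start-point tibble from [candidate_screen()].
#' @param block Equal-interval [block_spec()].
#' @param n_blocks Block repetitions.
#' @param config A [fit_config()].
#' @return An `mp_fit`: list with `theta` (named length-6), `cost`,
#'   `converged`, `winning_start`, `n_echo`, `tr_ip`.
#' @export
refine <- function(S, starts, block, n_blocks = 25, config = fit_config()) {
  pt <- block_pulse_table(block)
  nb <- as.integer(n_blocks)
  target <- c(Re(S), Im(S))
  resid_fn <- function(p) {
    u <- sim_train_cpp(pt$flip, pt$phase, nb, p[3], p[4], 1, p[5], p[6],
                       c(0, 0, 1))
    s <- complex(real = p[1], imaginary = p[2]) * as.vector(u)
    target - c(Re(s), Im(s))
  }
  lower <- c(-Inf, -Inf, config$e1_bounds[1], config$e2_bounds[1],
             config$beta_bounds[1], config$b1_bounds[1])
  upper <- c(Inf, Inf, config$e1_bounds[2], config$e2_bounds[2],
             config$beta_bounds[2], config$b1_bounds[2])
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    p0 <- as.numeric(starts[i, c("ReS0", "ImS0", "E1", "E2", "beta", "B1")])
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = p0, fn = resid_fn, lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = config$maxiter,
                                             ftol = 1e-12, ptol = 1e-12)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    cost <- fit$deviance
    conv <- fit$info %in% 1:4
    if (is.null(best) || cost < best$cost) {
      best <- list(theta = stats::setNames(fit$par,
                                           c("ReS0", "ImS0", "E1", "E2",
                                             "beta", "B1")),
                   cost = cost, converged = conv, winning_start = i)
    }
  }
  if (is.null(best) || !best$converged) {
    return(structure(list(theta = rep(NA_real_, 6), cost = NA_real_,
                          converged = FALSE, winning_start = NA_integer_,
                          n_echo = length(S), tr_ip = block$tr_ref),
                     class = "mp_fit"))
  }
  structure(c(best, list(n_echo = length(S), tr_ip = block$tr_ref)),
            class = "mp_fit")
}

#' Fit one echo train
#'
#' Convenience wrapper: [candidate_screen()] then [refine()].
#'
#' @inheritParams candidate_screen
#' @return An `mp_fit` (see [refine()]), or `NULL` for an empty voxel.
#' @export
fit_train <- function(S, block, n_blocks = 25, config = fit_config()) {
  starts <- candidate_screen(S, block, n_blocks, config)
  if (is.null(starts)) return(NULL)
  refine(S, starts, block, n_blocks, config)
}

#' @export
print.mp_fit <- function(x, ...) {
  cat("<mp_fit> converged:", x$converged, "\n")
  if (x$converged) {
    th <- x$theta
    cat("  T1 =", format(-x$tr_ip / log(th["E1"]), digits = 5),
        "ms  T2 =", format(-x$tr_ip / log(th["E2"]), digits = 5),
        "ms  cost =", format(x$cost, digits = 5), "\n")
  }
  invisible(x)
}

#' Fit every voxel of a simulated dataset
#'
#' Voxelwise multi-start fitting of the single-species model. The
#' candidate set and its unit model trains are drawn once (they do not
#' depend on the data) and screened against every voxel; each voxel is
#' then refined independently, so results are independent of traversal
#' order.
#'
#' @param dataset An [simulate_dataset()] result.
#' @param config A [fit_config()].
#' @param mask Logical voxel mask; defaults to the phantom's `mask`
#'   column (voxels with nonzero proton density).
#' @return An `mp_mapfit`: tibble with one row per fitted voxel (`x`,
#'   `y`, `vial`, estimates `ReS0 ... B1`, `cost`, `converged`,
#'   `winning_start`) plus `tr_ip`, `config` attributes.
#' @export
fit_dataset <- function(dataset, config = fit_config(), mask = NULL) {
  stopifnot(inherits(dataset, "mp_dataset"))
  ph <- dataset$phantom
  mask <- mask %||% ph$mask
  pt <- block_pulse_table(dataset$block)
  cand <- draw_candidates(config)
  U <- candidate_trains_cpp(cand, pt$flip, pt$phase,
                            as.integer(dataset$n_blocks))
  idx <- which(mask)
  rows <- vector("list", length(idx))
  for (k in seq_along(idx)) {
    i <- idx[k]
    S <- dataset$echoes[, i]
    starts <- screen_against(S, U, cand, config$n_starts)
    fit <- refine(S, starts, dataset$block, dataset$n_blocks, config)
    rows[[k]] <- tibble::tibble(
      x = ph$x[i], y = ph$y[i], vial = ph$vial[i],
      ReS0 = fit$theta[1], ImS0 = fit$theta[2], E1 = fit$theta[3],
      E2 = fit$theta[4], beta = fit$theta[5], B1 = fit$theta[6],
      cost = fit$cost, converged = fit$converged,
      winning_start = fit$winning_start
    )
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("mp_mapfit", class(out))
  attr(out, "tr_ip") <- dataset$tr_ip
  attr(out, "config") <- config
  out
}

#' Assemble parameter maps from voxelwise fits
#'
#' Converts the fitted decay factors to relaxation times
#' (`T = -tr_ip / ln E`, ms), proton density `|S0|` and transmit-receive
#' phase `arg S0`, the static-field offset in Hz
#' (`beta / (2 pi tr_ip)`, with `tr_ip` in seconds) and the per-block HO
#' dissipation `E2^2 E1` per inter-pulse interval (so
#' `ho^k` for a k-interval block). Estimates within
#' `censor_tol` of a bound are flagged `censored` rather than clipped.
#'
#' @param mapfit An [fit_dataset()] result.
#' @param censor_tol Distance to a bound (relative to the bound range)
#'   below which an estimate counts as censored.
#' @return Tibble: `x`, `y`, `vial`, `T1`, `T2`, `PD`, `phase`, `B0_hz`,
#'   `B1`, `HO`, `censored`, `cost`, `converged`.
#' @export
assemble_maps <- function(mapfit, censor_tol = 1e-4) {
  tr <- attr(mapfit, "tr_ip")
  cfg <- attr(mapfit, "config")
  near <- function(x, b) {
    w <- diff(b)
    (x - b[1]) < censor_tol * w | (b[2] - x) < censor_tol * w
  }
  safe_T <- function(e) ifelse(e >= 1 - 1e-12, NA_real_, -tr / log(e))
  dplyr::transmute(
    tibble::as_tibble(mapfit),
    x = .data$x, y = .data$y, vial = .data$vial,
    T1 = safe_T(.data$E1),
    T2 = safe_T(.data$E2),
    PD = sqrt(.data$ReS0^2 + .data$ImS0^2),
    phase = atan2(.data$ImS0, .data$ReS0),
    B0_hz = .data$beta / (2 * pi * tr * 1e-3),
    B1 = .data$B1,
    HO = .data$E2^2 * .data$E1,
    censored = near(.data$E1, cfg$e1_bounds) | near(.data$E2, cfg$e2_bounds),
    cost = .data$cost, converged = .data$converged
  )
}
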