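#' Affine operator of a single event
#'
#' @param event An [rf_event()] or [delay_event()].
#' @param vox A [voxel_params()].
#' @param tr_ref Reference inter-pulse period, ms.
#' @return List `(matrix, offset)`.
#' @keywords internal
event_operator <- function(event, vox, tr_ref) {
  if (event$type == "rf") {
    list(matrix = rf_rotation(vox$B1 * event$flip, event$phase),
         offset = c(0, 0, 0))
  } else {
    rel <- relaxation_operator(event$tau, vox$T1, vox$T2, vox$PD)
    ang <- if (tr_ref > 0) vox$beta * event$tau / tr_ref * 180 / pi else 0
    # precession and relaxation commute (both block-diagonal in the
    # transverse plane); relaxation-then-precession order is used
    list(matrix = rotation_matrix("z", ang) %*% rel$matrix,
         offset = rel$offset)
  }
}

#' Compose the block propagator
#'
#' Folds the ordered event operators of a block into the affine map
#' `m -> A m + c` over one repetition, and solves for the steady state
#' `m_ss = (I - A)^{-1} c`. When the block has no dissipation (pure
#' rotation), `(I - A)` is singular and the steady state is flagged as
#' non-unique (`steady_state = NULL`, `unique_steady_state = FALSE`);
#' callers may substitute the thermal equilibrium.
#'
#' @param block A [block_spec()].
#' @param vox A [voxel_params()].
#' @return A `propagator` object: list with `matrix` (A), `offset` (c),
#'   `steady_state`, `unique_steady_state`, `block`, `vox`.
#' @export
compose_block <- function(block, vox) {
  stopifnot(inherits(block, "block_spec"), inherits(vox, "voxel_params"))
  A <- diag(3)
  cvec <- c(0, 0, 0)
  for (e in block$events) {
    op <- event_operator(e, vox, block$tr_ref)
    A <- op$matrix %*% A
    cvec <- drop(op$matrix %*% cvec) + op$offset
  }
  IA <- diag(3) - A
  unique_ss <- abs(det(IA)) > 1e-12
  mss <- if (unique_ss) drop(solve(IA, cvec)) else NULL
  structure(
    list(matrix = A, offset = cvec, steady_state = mss,
         unique_steady_state = unique_ss, block = block, vox = vox),
    class = "propagator"
  )
}

#' @export
print.propagator <- function(x, ...) {
  cat("<propagator> 3x3 affine block map\n")
  cat("  det(A) =", format(det(x$matrix), digits = 10), "\n")
  if (x$unique_steady_state) {
    cat("  m_ss   =", format(x$steady_state, digits = 6), "\n")
  } else {
    cat("  no unique steady state (pure rotation block)\n")
  }
  invisible(x)
}

#' Block-recursion simulation
#'
#' Applies the affine block map repeatedly:
#' `m_{n+1} = A m_n + c`, reporting both the magnetization `m_n` and the
#' transient `mu_n = m_n - m_ss` for `n = 0, ..., n_blocks`.
#'
#' @param prop A [compose_block()] result.
#' @param m0 Initial magnetization (length-3). Default: thermal equilibrium
#'   `(0, 0, PD)`.
#' @param n_blocks Number of block applications (>= 0).
#' @return Tibble with columns `n`, `mx`, `my`, `mz`, `mux`, `muy`, `muz`.
#' @export
simulate_recursion <- function(prop, m0 = NULL, n_blocks = 25) {
  stopifnot(inherits(prop, "propagator"), n_blocks >= 0)
  if (is.null(m0)) m0 <- c(0, 0, prop$vox$PD)
  mss <- prop$steady_state %||% c(0, 0, 0)
  out <- matrix(NA_real_, nrow = n_blocks + 1L, ncol = 3)
  m <- as.numeric(m0)
  out[1L, ] <- m
  if (n_blocks > 0) {
    for (n in seq_len(n_blocks)) {
      m <- drop(prop$matrix %*% m) + prop$offset
      out[n + 1L, ] <- m
    }
  }
  tibble::tibble(
    n = 0:n_blocks,
    mx = out[, 1], my = out[, 2], mz = out[, 3],
    mux = out[, 1] - mss[1], muy = out[, 2] - mss[2], muz = out[, 3] - mss[3]
  )
}

#' Event-by-event echo-train simulation (reference path)
#'
#' Steps the magnetization through every event of every block repetition
#' and records the quadrature signal `s = mx + i my` immediately after
#' each readout event. This is the package's reference simulator; the
#' compiled fast path ([sim_train()]) is asserted against it.
#'
#' @param block A [block_spec()] with at least one readout.
#' @param vox A [voxel_params()].
#' @param n_blocks Number of block repetitions.
#' @param m0 Initial magnetization; default thermal equilibrium.
#' @return Tibble with columns `block`, `readout`, `echo`, `signal`
#'   (complex), carrying attributes `tr_ip` and `block_TR`.
#' @export
simulate_echoes <- function(block, vox, n_blocks = 25, m0 = NULL) {
  stopifnot(inherits(block, "block_spec"), inherits(vox, "voxel_params"))
  if (length(block$readout_indices) == 0L) {
    stop("block defines no readouts", call. = FALSE)
  }
  if (is.null(m0)) m0 <- c(0, 0, vox$PD)
  ops <- lapply(block$events, event_operator, vox = vox, tr_ref = block$tr_ref)
  is_ro <- seq_along(block$events) %in% block$readout_indices
  n_ro <- sum(is_ro)
  sig <- complex(n_blocks * n_ro)
  m <- as.numeric(m0)
  idx <- 0L
  for (b in seq_len(n_blocks)) {
    for (j in seq_along(ops)) {
      m <- drop(ops[[j]]$matrix %*% m) + ops[[j]]$offset
      if (is_ro[j]) {
        idx <- idx + 1L
        sig[idx] <- complex(real = m[1], imaginary = m[2])
      }
    }
  }
  out <- tibble::tibble(
    block = rep(seq_len(n_blocks), each = n_ro),
    readout = rep(seq_len(n_ro), times = n_blocks),
    echo = seq_len(n_blocks * n_ro),
    signal = sig
  )
  attr(out, "tr_ip") <- block$tr_ref
  attr(out, "block_TR") <- block$block_TR
  out
}

#' Fast echo-train simulation for equal-interval blocks
#'
#' Compiled equivalent of [simulate_echoes()] for blocks that alternate
#' single pulses with equal readout delays (the [scheme_block()] family).
#'
#' @inheritParams simulate_echoes
#' @return Complex vector of echoes in acquisition order.
#' @export
sim_train <- function(block, vox, n_blocks = 25, m0 = NULL) {
  pt <- block_pulse_table(block)
  if (is.null(m0)) m0 <- c(0, 0, vox$PD)
  e1 <- exp(-block$tr_ref / vox$T1)
  e2 <- exp(-block$tr_ref / vox$T2)
  as.vector(sim_train_cpp(pt$flip, pt$phase, as.integer(n_blocks),
                          e1, e2, vox$PD, vox$beta, vox$B1, as.numeric(m0)))
}

#' Total per-block dissipation (HO value)
#'
#' The determinant of any block propagator whose delays total `block_TR`:
#' `exp(-2 block_TR / T2) * exp(-block_TR / T1)`, independent of flip
#' angles, phases and off-resonance (rotations are volume preserving).
#' Applied voxelwise this is the HO (harmonic-oscillator) map.
#'
#' @param vox A [voxel_params()], or a data frame with `T1`, `T2` columns.
#' @param block_TR Total free-precession time of the block, ms.
#' @return Dimensionless dissipation value(s) in (0, 1].
#' @export
ho_value <- function(vox, block_TR) {
  exp(-2 * block_TR / vox$T2) * exp(-block_TR / vox$T1)
}
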