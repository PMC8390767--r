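#' Elementary rotation matrix
#'
#' Proper right-handed rotation about a lab axis. The rotation sense is
#' right-handed about the named axis; this convention is used consistently
#' throughout the package.
#'
#' @param axis One of `"x"`, `"y"`, `"z"`.
#' @param angle Rotation angle in degrees.
#' @return A real 3x3 orthogonal matrix with determinant 1.
#' @examples
#' rotation_matrix("z", 90)
#' @export
rotation_matrix <- function(axis, angle) {
  if (!is.character(axis) || length(axis) != 1L || !axis %in% c("x", "y", "z")) {
    stop("`axis` must be one of \"x\", \"y\", \"z\"", call. = FALSE)
  }
  stopifnot(is.numeric(angle), length(angle) == 1L, is.finite(angle))
  a <- angle * pi / 180
  ca <- cos(a); sa <- sin(a)
  switch(axis,
    x = matrix(c(1, 0, 0, 0, ca, sa, 0, -sa, ca), 3, 3),
    y = matrix(c(ca, 0, -sa, 0, 1, 0, sa, 0, ca), 3, 3),
    z = matrix(c(ca, sa, 0, -sa, ca, 0, 0, 0, 1), 3, 3)
  )
}

#' Rotation about a transverse axis at arbitrary azimuth
#'
#' An RF pulse with flip angle `flip` about an axis in the transverse plane
#' at azimuth `phase` (measured from x towards y, so phase 0 is the x axis
#' and phase 90 the y axis) is realized by conjugating the base rotation
#' with the phase: `Rz(phase) %*% Rx(flip) %*% Rz(-phase)`.
#'
#' @param flip Flip angle, degrees.
#' @param phase Axis azimuth, degrees.
#' @return A real 3x3 rotation matrix.
#' @export
rf_rotation <- function(flip, phase = 0) {
  rotation_matrix("z", phase) %*% rotation_matrix("x", flip) %*%
    rotation_matrix("z", -phase)
}

#' Relaxation operator over a free-precession interval
#'
#' Affine relaxation map for an interval of length `tau`:
#' `diag(exp(-tau/T2), exp(-tau/T2), exp(-tau/T1))` with longitudinal
#' recovery offset `(0, 0, PD * (1 - exp(-tau/T1)))` towards the thermal
#' equilibrium `(0, 0, PD)`.
#'
#' @param tau Interval length, ms (>= 0).
#' @param T1,T2 Relaxation times, ms (> 0; `Inf` allowed).
#' @param PD Proton density (equilibrium magnetization), arbitrary units.
#' @return List with elements `matrix` (3x3) and `offset` (length-3).
#' @export
relaxation_operator <- function(tau, T1, T2, PD = 1) {
  stopifnot(is.numeric(tau), length(tau) == 1L)
  if (tau < 0) stop("`tau` must be non-negative", call. = FALSE)
  stopifnot(T1 > 0, T2 > 0)
  e1 <- exp(-tau / T1)
  e2 <- exp(-tau / T2)
  list(matrix = diag(c(e2, e2, e1)), offset = c(0, 0, PD * (1 - e1)))
}

#' RF and delay events
#'
#' Constructors for the two event types making up an acquisition block.
#' An `rf_event` is an ideal (zero-duration) pulse with a flip angle and a
#' transverse-plane axis azimuth; a `delay_event` is a free-precession
#' interval during which relaxation and off-resonance precession act, and
#' after which an echo may be recorded (`readout = TRUE`).
#'
#' @param flip Flip angle, degrees (finite).
#' @param phase Axis azimuth, degrees; wrapped to `[0, 360)`.
#' @param tau Interval length, ms (>= 0).
#' @param readout Record an echo at the end of this delay?
#' @return An event object (list with class `"mp_event"`).
#' @export
rf_event <- function(flip, phase = 0) {
  stopifnot(is.finite(flip), is.finite(phase))
  structure(list(type = "rf", flip = flip, phase = phase %% 360),
            class = "mp_event")
}

#' @rdname rf_event
#' @export
delay_event <- function(tau, readout = FALSE) {
  stopifnot(is.numeric(tau), length(tau) == 1L)
  if (tau < 0) stop("`tau` must be non-negative", call. = FALSE)
  structure(list(type = "delay", tau = tau, readout = isTRUE(readout)),
            class = "mp_event")
}

#' Acquisition block specification
#'
#' An ordered list of RF and delay events defining one repeated propagator
#' block. `tr_ref` is the reference inter-pulse period (ms) over which the
#' off-resonance parameter `beta` of [voxel_params()] accrues: a delay of
#' length `tau` contributes a z-rotation of `beta * tau / tr_ref` radians.
#'
#' @param events List of events from [rf_event()] / [delay_event()].
#' @param tr_ref Reference inter-pulse period, ms. Defaults to the total
#'   free-precession time divided by the number of delays.
#' @return A `block_spec` object. Its `block_TR` is the total of delay
#'   lengths; `readout_indices` are the event positions after which echoes
#'   are recorded.
#' @export
block_spec <- function(events, tr_ref = NULL) {
  stopifnot(length(events) > 0L)
  ok <- vapply(events, function(e) inherits(e, "mp_event"), logical(1))
  if (!all(ok)) stop("all `events` must be created by rf_event()/delay_event()",
                     call. = FALSE)
  taus <- vapply(events, function(e) if (e$type == "delay") e$tau else 0,
                 numeric(1))
  n_delay <- sum(vapply(events, function(e) e$type == "delay", logical(1)))
  block_TR <- sum(taus)
  if (is.null(tr_ref)) {
    tr_ref <- if (n_delay > 0) block_TR / n_delay else 0
  }
  readout_indices <- which(vapply(events, function(e) {
    e$type == "delay" && e$readout
  }, logical(1)))
  structure(
    list(events = events, block_TR = block_TR, tr_ref = tr_ref,
         readout_indices = readout_indices),
    class = "block_spec"
  )
}

#' @export
print.block_spec <- function(x, ...) {
  k <- sum(vapply(x$events, function(e) e$type == "rf", logical(1)))
  cat("<block_spec> ", k, " RF pulse(s), block TR ", x$block_TR,
      " ms, ", length(x$readout_indices), " readout(s)\n", sep = "")
  invisible(x)
}

#' Named excitation schemes
#'
#' Builds the repeated blocks studied for transient-state mapping, with
#' equal inter-pulse spacing and one readout per interval:
#' \describe{
#'   \item{`"ax"`}{single pulse `alpha` about x.}
#'   \item{`"ax-ay"`}{two pulses `alpha` about x then y.}
#'   \item{`"ax-axd"`}{two pulses `alpha` about x and about the axis at
#'     azimuth `delta`.}
#'   \item{`"mp"`}{the four-pulse multi-phase block
#'     `alpha`(x) - `gamma`(y) - `alpha`(y) - `gamma`(x), the MP-b-nSSFP
#'     building block.}
#' }
#'
#' @param name Scheme name (see Details).
#' @param alpha,gamma Flip angles, degrees.
#' @param delta Axis azimuth offset for `"ax-axd"`, degrees.
#' @param tr_ip Inter-pulse period, ms.
#' @return A [block_spec()].
#' @export
scheme_block <- function(name = c("mp", "ax", "ax-ay", "ax-axd"),
                         alpha = 30, gamma = 175, delta = 75, tr_ip = 30) {
  name <- match.arg(name)
  pulses <- switch(name,
    "ax"     = list(c(alpha, 0)),
    "ax-ay"  = list(c(alpha, 0), c(alpha, 90)),
    "ax-axd" = list(c(alpha, 0), c(alpha, delta)),
    "mp"     = list(c(alpha, 0), c(gamma, 90), c(alpha, 90), c(gamma, 0))
  )
  events <- list()
  for (p in pulses) {
    events <- c(events, list(rf_event(p[1], p[2]), delay_event(tr_ip, TRUE)))
  }
  block_spec(events, tr_ref = tr_ip)
}

#' Per-pulse flip/phase table of an equal-interval block
#'
#' Helper used by the compiled fast path: valid for blocks that alternate
#' single RF pulses with equal readout delays (as produced by
#' [scheme_block()]).
#'
#' @param block A [block_spec()].
#' @return Tibble with columns `flip`, `phase` (degrees), and the attribute
#'   checked form, or an error if the block is not of this family.
#' @keywords internal
block_pulse_table <- function(block) {
  ev <- block$events
  n <- length(ev)
  if (n %% 2L != 0L) stop("block is not an alternating pulse/delay block",
                          call. = FALSE)
  types <- vapply(ev, `[[`, character(1), "type")
  if (!all(types == rep(c("rf", "delay"), n / 2L))) {
    stop("block is not an alternating pulse/delay block", call. = FALSE)
  }
  taus <- vapply(ev[seq(2L, n, 2L)], `[[`, numeric(1), "tau")
  ro <- vapply(ev[seq(2L, n, 2L)], `[[`, logical(1), "readout")
  if (length(unique(taus)) != 1L || !all(ro)) {
    stop("fast path requires equal delays each ending in a readout",
         call. = FALSE)
  }
  tibble::tibble(
    flip = vapply(ev[seq(1L, n, 2L)], `[[`, numeric(1), "flip"),
    phase = vapply(ev[seq(1L, n, 2L)], `[[`, numeric(1), "phase")
  )
}

#' Voxel parameter set
#'
#' Intrinsic (`T1`, `T2`, `PD`) and experimental (`beta`, `B1`) parameters
#' of a single species. `beta` is the off-resonance phase accrued per
#' reference inter-pulse period, radians; `B1` scales every flip angle.
#'
#' @param T1,T2 Relaxation times, ms; requires `0 < T2 <= T1`.
#' @param PD Proton density, arbitrary units (>= 0).
#' @param beta Off-resonance phase per inter-pulse period, radians.
#' @param B1 Transmit field scale (> 0).
#' @return A `voxel_params` object.
#' @export
voxel_params <- function(T1, T2, PD = 1, beta = 0, B1 = 1) {
  stopifnot(T1 > 0, T2 > 0, PD >= 0, B1 > 0)
  if (T2 > T1) stop("requires T2 <= T1", call. = FALSE)
  structure(list(T1 = T1, T2 = T2, PD = PD, beta = beta, B1 = B1),
            class = "voxel_params")
}

#' Read / write a block specification as YAML
#'
#' Serializes a [block_spec()] as a list of
#' `{type: rf|delay, flip, phase, tau, readout}` entries with `tr_ref`.
#'
#' @param block A [block_spec()].
#' @param path File path.
#' @return `write_block_yaml()` returns `path` invisibly;
#'   `read_block_yaml()` returns a [block_spec()].
#' @export
write_block_yaml <- function(block, path) {
  ev <- lapply(block$events, function(e) {
    if (e$type == "rf") {
      list(type = "rf", flip = e$flip, phase = e$phase)
    } else {
      list(type = "delay", tau = e$tau, readout = e$readout)
    }
  })
  yaml::write_yaml(list(tr_ref = block$tr_ref, events = ev), path)
  invisible(path)
}

#' @rdname write_block_yaml
#' @export
read_block_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  events <- lapply(x$events, function(e) {
    if (identical(e$type, "rf")) {
      rf_event(e$flip, e$phase %||% 0)
    } else if (identical(e$type, "delay")) {
      delay_event(e$tau, isTRUE(e$readout))
    } else {
      stop("unknown event type in ", path, call. = FALSE)
    }
  })
  block_spec(events, tr_ref = x$tr_ref)
}
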