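# Independent brute-force oracles, built from first principles (Rodrigues
# rotations, explicit exponentials) so they share no code with the package.

# rotation about unit axis `u` by `deg` degrees (Rodrigues formula)
h_rodrigues <- function(u, deg) {
  th <- deg * pi / 180
  u <- u / sqrt(sum(u^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# one pass of a block, stepping the 3-vector event by event
h_step_block <- function(block, vox, m) {
  for (e in block$events) {
    if (e$type == "rf") {
      ax <- c(cos(e$phase * pi / 180), sin(e$phase * pi / 180), 0)
      m <- drop(h_rodrigues(ax, vox$B1 * e$flip) %*% m)
    } else {
      if (block$tr_ref > 0) {
        ang <- vox$beta * e$tau / block$tr_ref
        m <- drop(h_rodrigues(c(0, 0, 1), ang * 180 / pi) %*% m)
      }
      e2 <- exp(-e$tau / vox$T2)
      e1 <- exp(-e$tau / vox$T1)
      m <- c(e2 * m[1], e2 * m[2], e1 * m[3] + vox$PD * (1 - e1))
    }
  }
  m
}

# echoes recorded event-by-event, mirroring the readout convention
h_sim_echoes <- function(block, vox, n_blocks, m0 = c(0, 0, vox$PD)) {
  m <- m0
  out <- complex(0)
  for (b in seq_len(n_blocks)) {
    for (j in seq_along(block$events)) {
      e <- block$events[[j]]
      if (e$type == "rf") {
        ax <- c(cos(e$phase * pi / 180), sin(e$phase * pi / 180), 0)
        m <- drop(h_rodrigues(ax, vox$B1 * e$flip) %*% m)
      } else {
        if (block$tr_ref > 0) {
          ang <- vox$beta * e$tau / block$tr_ref
          m <- drop(h_rodrigues(c(0, 0, 1), ang * 180 / pi) %*% m)
        }
        e2 <- exp(-e$tau / vox$T2)
        e1 <- exp(-e$tau / vox$T1)
        m <- c(e2 * m[1], e2 * m[2], e1 * m[3] + vox$PD * (1 - e1))
      }
      if (j %in% block$readout_indices) {
        out <- c(out, complex(real = m[1], imaginary = m[2]))
      }
    }
  }
  out
}

# random acquisition block: k pulses, uneven delays summing to block TR
h_random_block <- function(k = sample(1:4, 1), block_TR = 40) {
  taus <- stats::runif(k)
  taus <- taus / sum(taus) * block_TR
  events <- list()
  for (j in seq_len(k)) {
    events <- c(events, list(
      rf_event(stats::runif(1, 5, 170), stats::runif(1, 0, 360)),
      delay_event(taus[j], readout = TRUE)
    ))
  }
  block_spec(events, tr_ref = block_TR / k)
}

h_random_vox <- function() {
  T1 <- stats::runif(1, 300, 2000)
  voxel_params(T1 = T1, T2 = stats::runif(1, 30, min(300, T1)),
               PD = stats::runif(1, 0.5, 1.5),
               beta = stats::runif(1, -pi, pi),
               B1 = stats::runif(1, 0.7, 1.3))
}

# iterated matrix product, the oracle for closed-form powers
h_matpow <- function(A, n) {
  out <- diag(3)
  for (i in seq_len(n)) out <- A %*% out
  out
}
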