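fig2_prop <- function(beta = 14 * pi / 180) {
  compose_block(scheme_block("ax", 30, tr_ip = 10),
                voxel_params(878, 47.5, beta = beta))
}

test_that("eigen-parametrization handles identity, rotations and blocks", {
  et_i <- eigen_parametrize(diag(3))
  expect_equal(et_i$rho, 1)
  expect_equal(et_i$phi, 0)
  expect_equal(et_i$eta, 1)
  et_r <- eigen_parametrize(rotation_matrix("z", 25))
  expect_true(et_r$oscillatory)
  expect_equal(et_r$rho, 1, tolerance = 1e-12)
  expect_equal(et_r$phi, 25 * pi / 180, tolerance = 1e-12)
  expect_equal(et_r$eta, 1, tolerance = 1e-12)
  A <- fig2_prop(0)$matrix
  et <- eigen_parametrize(A)
  expect_equal(et$rho^2 * et$eta, det(A), tolerance = 1e-12)
  expect_error(eigen_parametrize(matrix(0, 3, 3)), "singular")
})

test_that("rho^2 eta equals the block dissipation for random propagators", {
  set.seed(7)
  for (i in 1:30) {
    b <- h_random_block()
    v <- h_random_vox()
    et <- eigen_parametrize(compose_block(b, v)$matrix)
    if (is.na(et$oscillatory)) next
    expect_equal(et$rho^2 * et$eta, exp(-2 * 40 / v$T2) * exp(-40 / v$T1),
                 tolerance = 1e-10)
  }
})

test_that("closed-form power equals iterated multiplication", {
  A <- fig2_prop()$matrix
  expect_equal(putzer_power(A, 0), diag(3))
  expect_equal(putzer_power(A, 1), A, tolerance = 1e-12)
  expect_equal(putzer_power(A, 137), h_matpow(A, 137), tolerance = 1e-9,
               ignore_attr = TRUE)
  set.seed(8)
  for (i in 1:60) {
    p <- compose_block(h_random_block(), h_random_vox())
    n <- sample(c(2:10, 50, 137, 500), 1)
    expect_equal(putzer_power(p$matrix, n), h_matpow(p$matrix, n),
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("closed-form power survives near-degenerate eigenvalues", {
  # tiny flip and off-resonance force |phi| < 1e-6
  for (alpha in c(0, 1e-5)) {
    blk <- scheme_block("ax", alpha, tr_ip = 10)
    v <- voxel_params(878, 47.5, beta = 1e-7)
    A <- compose_block(blk, v)$matrix
    for (n in c(0, 1, 3, 25, 200)) {
      expect_equal(putzer_power(A, n), h_matpow(A, n), tolerance = 1e-9)
    }
  }
  # triple-degenerate: pure relaxation with T1 = T2
  A3 <- relaxation_operator(10, 100, 100)$matrix
  expect_equal(putzer_power(A3, 7), h_matpow(A3, 7), tolerance = 1e-12)
  # mixed-sign real pair (180-degree pulse): falls back to the limit form
  A180 <- compose_block(scheme_block("ax", 180, tr_ip = 10),
                        voxel_params(878, 47.5))$matrix
  expect_equal(putzer_power(A180, 9), h_matpow(A180, 9), tolerance = 1e-9)
})

test_that("mode matrices satisfy their structural identities", {
  p <- fig2_prop()
  pm <- putzer_matrices(p$matrix)
  expect_equal(pm$M2, diag(3) - pm$M3, tolerance = 1e-12)
  # M3 is the spectral projector onto the real-eigenvalue direction
  expect_equal(pm$M3 %*% pm$M3, pm$M3, tolerance = 1e-10)
  mu0 <- c(0.3, -0.2, 0.5)
  nm <- normal_modes(p$matrix, mu0)
  expect_equal(nm$n2 + nm$n3, mu0, tolerance = 1e-10)
})

test_that("normal-mode expansion reconstructs the matrix-power evolution", {
  set.seed(9)
  for (i in 1:20) {
    p <- compose_block(h_random_block(), h_random_vox())
    et <- eigen_parametrize(p$matrix)
    if (is.na(et$oscillatory)) next
    if (min(Mod(et$values[1] - et$values[2]),
            Mod(et$values[1] - et$values[3]),
            Mod(et$values[2] - et$values[3])) /
        max(Mod(et$values)) < 1e-8) next
    mu0 <- c(0, 0, p$vox$PD) - p$steady_state
    nm <- normal_modes(p$matrix, mu0)
    mu <- mu_closed_form(nm, 0:60)
    for (n in c(0, 1, 7, 30, 60)) {
      expect_equal(unname(mu[n + 1, ]),
                   drop(putzer_power(p$matrix, n) %*% mu0), tolerance = 1e-9)
    }
  }
})

test_that("the third mode vanishes exactly on resonance for one excitation", {
  p <- fig2_prop(0)
  mu0 <- c(0, 0, 1) - p$steady_state
  nm <- normal_modes(p$matrix, mu0)
  expect_lt(nm$norms[3], 1e-10)
  expect_true(nm$vanished[3])
  # off resonance all three modes survive
  pb <- fig2_prop()
  nmb <- normal_modes(pb$matrix, c(0, 0, 1) - pb$steady_state)
  expect_true(all(nmb$norms > 1e-3))
})

test_that("two phase-distinct excitations keep all modes at every beta", {
  betas <- seq(0, 2 * pi, length.out = 65)[-65]
  blk <- scheme_block("ax-ay", 30, tr_ip = 12)
  mins <- vapply(betas, function(b) {
    p <- compose_block(blk, voxel_params(878, 47.5, beta = b))
    min(normal_modes(p$matrix, c(0, 0, 1) - p$steady_state)$norms)
  }, numeric(1))
  expect_true(all(mins > 1e-3))
})

test_that("quadrature closed form reproduces the recursion exactly", {
  p <- fig2_prop()
  mu0 <- c(0, 0, 1) - p$steady_state
  sm <- signal_model_params(p$matrix, mu0)
  rec <- simulate_recursion(p, n_blocks = 50)
  s_rec <- complex(real = rec$mux, imaginary = rec$muy)
  expect_equal(signal_closed_form(sm, 0:50), s_rec, tolerance = 1e-9)
  # transient decays to zero
  expect_lt(Mod(signal_closed_form(sm, 500)), 1e-10)
  # zero initial transient gives identically zero model
  sm0 <- signal_model_params(p$matrix, c(0, 0, 0))
  expect_equal(sm0$a, 0)
  expect_equal(sm0$b, 0)
  expect_equal(Mod(signal_closed_form(sm0, 0:10)), rep(0, 11))
})

test_that("on resonance the transverse projection degenerates to a line", {
  p <- fig2_prop(0)
  sm <- signal_model_params(p$matrix, c(0, 0, 1) - p$steady_state)
  expect_equal(sm$counter_amplitude, sm$a, tolerance = 1e-10)
})

test_that("continuous interpolant passes through the discrete states", {
  p <- fig2_prop()
  mu0 <- c(0, 0, 1) - p$steady_state
  y0 <- continuous_interpolant(p$matrix, 10, 0, mu0)
  expect_equal(unname(drop(y0)), mu0, tolerance = 1e-12)
  y7 <- continuous_interpolant(p$matrix, 10, 70, mu0)
  expect_equal(unname(drop(y7)), drop(putzer_power(p$matrix, 7) %*% mu0),
               tolerance = 1e-9)
  # smooth between block boundaries: half-step point sits close to the
  # neighbouring discrete states, no jump
  y <- continuous_interpolant(p$matrix, 10, c(0, 5, 10, 5 + 1e-6), mu0)
  expect_lt(max(abs(y[4, ] - y[2, ])), 1e-5)
  step <- sqrt(sum((y[3, ] - y[1, ])^2))
  expect_lt(sqrt(sum((y[2, ] - y[1, ])^2)), step)
  expect_error(continuous_interpolant(diag(c(-0.5, 0.5, 0.3)), 10, 5, mu0),
               "negative real axis")
})
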