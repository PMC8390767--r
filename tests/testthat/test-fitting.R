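mp30 <- scheme_block("mp", 30, 175, tr_ip = 30)

truth_theta <- function(T1 = 800, T2 = 90, beta = 1.2, b1 = 1.05,
                        s0 = 0.9 + 0.3i) {
  c(Re(s0), Im(s0), exp(-30 / T1), exp(-30 / T2), beta, b1)
}

test_that("forward model is linear in S0 and matches the simulator", {
  th <- truth_theta()
  expect_equal(forward_model(c(0, 0, th[3:6]), mp30, 10),
               rep(0 + 0i, 40))
  s1 <- forward_model(th, mp30, 25)
  s2 <- forward_model(c(2 * th[1:2], th[3:6]), mp30, 25)
  expect_equal(s2, 2 * s1, tolerance = 1e-12)
  vox <- voxel_params(800, 90, PD = 1, beta = 1.2, B1 = 1.05)
  expect_equal(forward_model(truth_theta(s0 = 1), mp30, 25),
               sim_train(mp30, vox, 25), tolerance = 1e-10)
  # E = 1 is the infinite-relaxation-time limit
  th_inf <- c(1, 0, 1, 1, 0.3, 1)
  expect_true(all(is.finite(Mod(forward_model(th_inf, mp30, 10)))))
})

test_that("candidate screening is reproducible and ranks the truth first", {
  th <- truth_theta()
  S <- forward_model(th, mp30, 25)
  cfg <- fit_config(seed = 10)
  s1 <- candidate_screen(S, mp30, 25, cfg)
  s2 <- candidate_screen(S, mp30, 25, cfg)
  expect_identical(s1, s2)
  expect_equal(nrow(s1), 5L)
  expect_true(all(diff(s1$cost) >= 0))
  expect_warning(out <- candidate_screen(rep(0 + 0i, 100), mp30, 25, cfg),
                 "empty voxel")
  expect_null(out)
})

test_that("closed-form S0 beats a dense grid over the complex scale", {
  th <- truth_theta()
  S <- forward_model(th, mp30, 25) +
    complex(real = rnorm(100, sd = 0.01), imaginary = rnorm(100, sd = 0.01))
  u <- forward_model(c(1, 0, th[3:6]), mp30, 25)
  s0_cf <- sum(Conj(u) * S) / sum(Mod(u)^2)
  cost_cf <- sum(Mod(S - s0_cf * u)^2)
  grid <- seq(-1.5, 1.5, length.out = 61)
  cost_grid <- min(outer(grid, grid, function(a, b) {
    vapply(seq_along(a), function(i) {
      sum(Mod(S - complex(real = a[i], imaginary = b[i]) * u)^2)
    }, numeric(1))
  }))
  expect_lte(cost_cf, cost_grid + 1e-12)
})

test_that("noiseless refinement recovers the truth to optimizer precision", {
  th <- truth_theta()
  S <- forward_model(th, mp30, 25)
  fit <- fit_train(S, mp30, 25, fit_config(seed = 3))
  expect_true(fit$converged)
  expect_equal(unname(fit$theta[3]), th[3], tolerance = 1e-6)
  expect_equal(unname(fit$theta[4]), th[4], tolerance = 1e-6)
  expect_lt(abs(fit$theta[5] - th[5]), 1e-6)
  expect_lt(fit$cost, 1e-12)
  # estimates respect the bounds
  cfg <- fit_config()
  expect_true(fit$theta[3] >= cfg$e1_bounds[1] &&
                fit$theta[3] <= cfg$e1_bounds[2])
  expect_true(fit$theta[4] >= cfg$e2_bounds[1] &&
                fit$theta[4] <= cfg$e2_bounds[2])
})

test_that("refinement never exceeds the screened cost and beats the truth", {
  set.seed(12)
  th <- truth_theta()
  S <- forward_model(th, mp30, 25) +
    complex(real = rnorm(100, sd = 0.01), imaginary = rnorm(100, sd = 0.01))
  cfg <- fit_config(seed = 4)
  starts <- candidate_screen(S, mp30, 25, cfg)
  fit <- refine(S, starts, mp30, 25, cfg)
  expect_lte(fit$cost, min(starts$cost) + 1e-12)
  cost_truth <- sum(Mod(S - forward_model(th, mp30, 25))^2)
  expect_lte(fit$cost, cost_truth)
})

test_that("noiseless identifiability holds for every off-resonance", {
  cfg <- fit_config(seed = 5)
  for (b in seq(-pi, pi, length.out = 17)[-17]) {
    th <- truth_theta(beta = b)
    fit <- fit_train(forward_model(th, mp30, 25), mp30, 25, cfg)
    expect_true(fit$converged)
    expect_equal(unname(fit$theta[3:5]), th[3:5], tolerance = 1e-5)
  }
})

test_that("map assembly applies the unit conversions", {
  mf <- tibble::tibble(
    x = 1:2, y = 1L, vial = 1L,
    ReS0 = c(1, 0.5), ImS0 = 0, E1 = c(exp(-1), 1), E2 = exp(-0.5),
    beta = c(2 * pi, pi), B1 = 1.1, cost = 0, converged = TRUE,
    winning_start = 1L
  )
  class(mf) <- c("mp_mapfit", class(mf))
  attr(mf, "tr_ip") <- 30
  attr(mf, "config") <- fit_config()
  maps <- assemble_maps(mf)
  expect_equal(maps$T1[1], 30)
  expect_equal(maps$T2[1], 60)
  expect_equal(maps$B0_hz[1], 1 / 0.030, tolerance = 1e-12)
  expect_equal(maps$HO, exp(-0.5)^2 * mf$E1, tolerance = 1e-12)
  # E at the upper bound is censored, not infinite
  expect_true(is.na(maps$T1[2]))
  expect_true(maps$censored[2])
})

test_that("fitting a small phantom recovers the ground-truth maps", {
  lay <- vial_layout(32)[c(1, 5, 9, 12), ]
  ph <- make_vial_phantom(lay, n_grid = 32)
  ds <- simulate_dataset(ph, snr = 60, seed = 21)
  mf <- fit_dataset(ds, fit_config(seed = 6))
  expect_equal(nrow(mf), sum(ph$mask))
  expect_true(all(mf$converged))
  maps <- assemble_maps(mf)
  truth <- ph[ph$mask, ]
  for (v in unique(truth$vial)) {
    t1_hat <- stats::median(maps$T1[maps$vial == v])
    t2_hat <- stats::median(maps$T2[maps$vial == v])
    expect_equal(t1_hat, truth$T1[truth$vial == v][1], tolerance = 0.05)
    expect_equal(t2_hat, truth$T2[truth$vial == v][1], tolerance = 0.05)
  }
  expect_gt(stats::cor(maps$B0_hz, truth$B0_hz), 0.99)
})

test_that("tidiers expose estimates and fit summaries", {
  th <- truth_theta()
  fit <- fit_train(forward_model(th, mp30, 25), mp30, 25, fit_config(seed = 3))
  td <- tidy(fit)
  expect_true(all(c("E1", "T1", "T2", "PD", "B0_hz") %in% td$term))
  expect_equal(td$estimate[td$term == "T1"], 800, tolerance = 1e-4)
  gl <- glance(fit)
  expect_true(gl$converged)
  expect_equal(gl$n_echo, 100L)
})
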