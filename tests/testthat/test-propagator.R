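test_that("a block without excitation leaves equilibrium fixed", {
  blk <- block_spec(list(rf_event(0, 0), delay_event(10, TRUE)))
  vox <- voxel_params(878, 47.5, PD = 0.8)
  p <- compose_block(blk, vox)
  expect_equal(p$matrix, relaxation_operator(10, 878, 47.5)$matrix)
  expect_equal(p$steady_state, c(0, 0, 0.8), tolerance = 1e-12)
})

test_that("block determinant equals the dissipation, independent of angles", {
  vox <- voxel_params(878, 47.5, beta = 0)
  blk <- scheme_block("ax", 30, tr_ip = 10)
  p <- compose_block(blk, vox)
  expect_equal(det(p$matrix), exp(-2 * 10 / 47.5) * exp(-10 / 878),
               tolerance = 1e-12)
  set.seed(3)
  for (i in 1:100) {
    b <- h_random_block(block_TR = 40)
    v <- h_random_vox()
    expect_equal(det(compose_block(b, v)$matrix),
                 exp(-2 * 40 / v$T2) * exp(-40 / v$T1),
                 tolerance = 1e-10)
  }
})

test_that("steady state is a fixed point of the affine map", {
  set.seed(4)
  for (i in 1:25) {
    b <- h_random_block()
    v <- h_random_vox()
    p <- compose_block(b, v)
    expect_lt(max(abs(drop(p$matrix %*% p$steady_state) + p$offset -
                        p$steady_state)), 1e-10)
  }
})

test_that("pure rotation blocks are flagged as having no unique steady state", {
  blk <- scheme_block("ax", 30, tr_ip = 10)
  vox <- voxel_params(Inf, Inf, PD = 1, beta = 0.3)
  p <- compose_block(blk, vox)
  expect_false(p$unique_steady_state)
  expect_null(p$steady_state)
})

test_that("composed affine map agrees with event-by-event stepping", {
  set.seed(5)
  for (i in 1:50) {
    b <- h_random_block()
    v <- h_random_vox()
    p <- compose_block(b, v)
    m_aff <- c(0, 0, v$PD)
    m_step <- m_aff
    for (n in 1:200) {
      m_aff <- drop(p$matrix %*% m_aff) + p$offset
      m_step <- h_step_block(b, v, m_step)
    }
    expect_lt(max(abs(m_aff - m_step)), 1e-10)
  }
})

test_that("zero flip angles give exact mono-exponential T1 recovery", {
  blk <- block_spec(list(rf_event(0, 0), delay_event(25, TRUE)))
  vox <- voxel_params(600, 80, PD = 1)
  p <- compose_block(blk, vox)
  rec <- simulate_recursion(p, m0 = c(0, 0, 0.2), n_blocks = 30)
  n <- 0:30
  expect_equal(rec$mz, 1 - (1 - 0.2) * exp(-n * 25 / 600), tolerance = 1e-12)
  expect_equal(rec$mx, rep(0, 31))
})

test_that("recursion endpoints and steady-state behaviour", {
  blk <- scheme_block("mp", 30, 175, tr_ip = 30)
  vox <- voxel_params(800, 90, beta = 0.7)
  p <- compose_block(blk, vox)
  r0 <- simulate_recursion(p, m0 = c(0.1, 0.2, 0.3), n_blocks = 0)
  expect_equal(nrow(r0), 1L)
  expect_equal(unlist(r0[1, c("mx", "my", "mz")], use.names = FALSE),
               c(0.1, 0.2, 0.3))
  rss <- simulate_recursion(p, m0 = p$steady_state, n_blocks = 10)
  expect_lt(max(abs(rss$mux), abs(rss$muy), abs(rss$muz)), 1e-12)
  # transients vanish because all eigenvalue magnitudes are below 1
  expect_true(all(Mod(eigen(p$matrix)$values) < 1))
  r <- simulate_recursion(p, n_blocks = 2000)
  expect_lt(max(abs(r$mux[2001]), abs(r$muy[2001]), abs(r$muz[2001])), 1e-12)
})

test_that("echo trains have protocol length and match the stepping oracle", {
  blk <- scheme_block("mp", 30, 175, tr_ip = 30)
  vox <- voxel_params(800, 90, PD = 0.9, beta = 0.6, B1 = 1.08)
  ec <- simulate_echoes(blk, vox, n_blocks = 25)
  expect_equal(nrow(ec), 100L)
  expect_equal(ec$signal, h_sim_echoes(blk, vox, 25), tolerance = 1e-12)
  # zero proton density gives a silent train
  ec0 <- simulate_echoes(blk, voxel_params(800, 90, PD = 0), 5)
  expect_equal(max(Mod(ec0$signal)), 0)
  # no readouts is an error
  b2 <- block_spec(list(rf_event(30, 0), delay_event(10, FALSE)))
  expect_error(simulate_echoes(b2, vox, 5), "readout")
})

test_that("block-boundary echoes equal the recursion's transverse state", {
  blk <- scheme_block("ax", 30, tr_ip = 10)   # one readout, at block end
  vox <- voxel_params(878, 47.5, beta = 0.4)
  p <- compose_block(blk, vox)
  rec <- simulate_recursion(p, n_blocks = 20)
  ec <- simulate_echoes(blk, vox, n_blocks = 20)
  expect_equal(ec$signal,
               complex(real = rec$mx[-1], imaginary = rec$my[-1]),
               tolerance = 1e-12)
})

test_that("compiled fast path equals the reference simulator", {
  set.seed(6)
  for (i in 1:10) {
    v <- h_random_vox()
    blk <- scheme_block(sample(c("mp", "ax", "ax-ay"), 1),
                        alpha = runif(1, 10, 90), gamma = runif(1, 90, 180),
                        tr_ip = runif(1, 5, 40))
    expect_equal(sim_train(blk, v, 12), simulate_echoes(blk, v, 12)$signal,
                 tolerance = 1e-12)
  }
})
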