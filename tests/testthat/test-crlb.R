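test_that("exactly ten unique four-pulse axis patterns exist", {
  sch <- enumerate_k4_schemes()
  expect_equal(nrow(sch), 10L)
  expect_equal(anyDuplicated(sch$scheme), 0L)
  # every pattern's reversal is already represented
  for (p in sch$scheme) {
    r <- paste(rev(strsplit(p, "")[[1]]), collapse = "")
    expect_true(min(p, r) %in% sch$scheme)
  }
  expect_true("xyyx" %in% sch$scheme)   # the multi-phase building block
})

test_that("signal Jacobian is exact in S0 and stable under step halving", {
  blk <- scheme_block("mp", 30, 175, tr_ip = 30)
  theta <- c(0.8, 0.1, exp(-30 / 800), exp(-30 / 90), 0.5, 1.02)
  J <- signal_jacobian(theta, blk, n_blocks = 25)
  u <- forward_model(c(1, 0, theta[3:6]), blk, 25)
  expect_equal(J[, "ReS0"], c(Re(u), Im(u)), tolerance = 1e-12)
  expect_equal(J[, "ImS0"], c(-Im(u), Re(u)), tolerance = 1e-12)
  Jh <- signal_jacobian(theta, blk, 25, rel_step = 5e-7)
  for (col in c("E1", "E2", "beta", "B1")) {
    expect_equal(J[, col], Jh[, col], tolerance = 1e-5)
  }
})

test_that("CV scales with noise and does not grow with more echoes", {
  blk <- scheme_block("mp", 30, 175, tr_ip = 30)
  vox <- voxel_params(800, 90, beta = 0.5)
  cv1 <- crlb_cv(blk, vox, sigma = 0.005)
  cv2 <- crlb_cv(blk, vox, sigma = 0.010)
  expect_equal(cv2$cv_t1 / cv1$cv_t1, 2, tolerance = 1e-6)
  expect_equal(cv2$cv_t2 / cv1$cv_t2, 2, tolerance = 1e-6)
  cv_more <- crlb_cv(blk, vox, sigma = 0.005, n_blocks = 50)
  expect_lte(cv_more$cv_t1, cv1$cv_t1 * (1 + 1e-9))
  expect_lte(cv_more$cv_t2, cv1$cv_t2 * (1 + 1e-9))
})

test_that("a block with no excitation is reported as non-identifiable", {
  blk <- scheme_block("ax", 0, tr_ip = 30)
  cv <- crlb_cv(blk, voxel_params(800, 90))
  expect_false(cv$identifiable)
})

test_that("on-resonance single-pulse signal carries no eta information", {
  # derivative of the transient along the eta eigen-direction is
  # n eta^(n-1) M3 mu0, identically zero because n3 = M3 mu0 = 0: the
  # Fisher matrix in the eigen-parametrization has a zero eta column
  p <- compose_block(scheme_block("ax", 30, tr_ip = 10),
                     voxel_params(878, 47.5, beta = 0))
  mu0 <- c(0, 0, 1) - p$steady_state
  nm <- normal_modes(p$matrix, mu0)
  n <- 1:100
  eta_col <- outer(n * nm$eigen$eta^(n - 1), nm$n3)
  expect_lt(max(abs(eta_col)), 1e-10)
  # off resonance the same column is non-zero
  pb <- compose_block(scheme_block("ax", 30, tr_ip = 10),
                      voxel_params(878, 47.5, beta = 0.4))
  nmb <- normal_modes(pb$matrix, c(0, 0, 1) - pb$steady_state)
  expect_gt(max(abs(outer(n * nmb$eigen$eta^(n - 1), nmb$n3))), 1e-3)
})

test_that("grid search on a single point returns that point", {
  res <- grid_search(schemes = enumerate_k4_schemes()[8, ],
                     alpha_grid = 30, gamma_grid = 175,
                     beta_grid = seq(0, 2 * pi, length.out = 5)[-5])
  expect_equal(nrow(res$aggregate), 1L)
  expect_equal(res$best$alpha, 30)
  expect_equal(res$best$gamma, 175)
  expect_true(is.finite(res$best$cv_worst))
})

test_that("aggregate equals the worst case over tissues and beta", {
  sch <- enumerate_k4_schemes()
  i <- which(sch$scheme == "xyyx")
  res <- grid_search(schemes = sch[i, ], alpha_grid = c(30, 60),
                     gamma_grid = c(90, 175),
                     beta_grid = seq(0, 2 * pi, length.out = 5)[-5],
                     keep_full = TRUE)
  full <- res$full
  agg <- res$aggregate
  for (r in seq_len(nrow(agg))) {
    sub <- full[full$alpha == agg$alpha[r] & full$gamma == agg$gamma[r], ]
    expect_equal(agg$cv_t1_max[r], max(sub$cv_t1))
    expect_equal(agg$cv_t2_max[r], max(sub$cv_t2))
  }
})

test_that("the selected scheme's CV depends only weakly on beta", {
  blk <- scheme_block("mp", 30, 175, tr_ip = 30)
  tis <- design_tissues()
  for (t in seq_len(nrow(tis))) {
    cv <- vapply(seq(0, 2 * pi, length.out = 9)[-9], function(b) {
      unlist(crlb_cv(blk, voxel_params(tis$T1[t], tis$T2[t], beta = b))[
        , c("cv_t1", "cv_t2")])
    }, numeric(2))
    expect_lt(max(cv[1, ]) / min(cv[1, ]), 1.5)
    expect_lt(max(cv[2, ]) / min(cv[2, ]), 1.5)
  }
})
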