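#' Enumerate the unique four-pulse axis patterns
#'
#' All assignments of x/y excitation axes to a four-pulse block carrying
#' two alternating flip angles (`alpha, gamma, alpha, gamma`), counted
#' once per equivalence class under reversal of the pulse order within the
#' block (a reversed block is the same pulse set traversed backwards and
#' carries the same information content). Sixteen raw patterns, four of
#' them palindromic, give exactly ten unique schemes.
#'
#' @return Tibble with `scheme` (e.g. `"xyyx"`), `phases` (list column of
#'   axis azimuths in degrees) and `flip_is_gamma` (list column, which
#'   pulses carry the `gamma` flip).
#' @export
enumerate_k4_schemes <- function() {
  axes <- c("x", "y")
  pats <- do.call(paste0, expand.grid(axes, axes, axes, axes,
                                      stringsAsFactors = FALSE)[, 4:1])
  canon <- vapply(pats, function(p) {
    r <- paste(rev(strsplit(p, "")[[1]]), collapse = "")
    min(p, r)
  }, character(1))
  pats <- sort(unique(canon))
  tibble::tibble(
    scheme = pats,
    phases = lapply(pats, function(p) {
      ifelse(strsplit(p, "")[[1]] == "x", 0, 90)
    }),
    flip_is_gamma = rep(list(c(FALSE, TRUE, FALSE, TRUE)), length(pats))
  )
}

#' Jacobian of the detected echo train
#'
#' Partial derivatives of the real/imaginary-stacked echo train with
#' respect to `theta = [Re S0, Im S0, E1, E2, beta, B1]`. The `S0` columns
#' are exact (the signal is linear in `S0`); the remaining four use
#' central finite differences with relative step `rel_step`.
#'
#' @param theta Length-6 numeric vector (see above); `E1`, `E2` are the
#'   per-interval decay factors `exp(-tr_ip / T)`.
#' @param block An equal-interval [block_spec()] (see [scheme_block()]).
#' @param n_blocks Number of block repetitions.
#' @param rel_step Relative finite-difference step.
#' @return `2 * n_echo` x 6 real matrix.
#' @export
signal_jacobian <- function(theta, block, n_blocks = 25, rel_step = 1e-6) {
  stopifnot(length(theta) == 6, all(is.finite(theta)))
  pt <- block_pulse_table(block)
  J <- signal_jacobian_cpp(pt$flip, pt$phase, as.integer(n_blocks),
                           theta[1], theta[2], theta[3], theta[4],
                           theta[5], theta[6], rel_step)
  colnames(J) <- c("ReS0", "ImS0", "E1", "E2", "beta", "B1")
  J
}

#' Cramer-Rao coefficients of variation for T1 and T2
#'
#' Fisher information `F = J^T J / sigma^2` for i.i.d. circular complex
#' Gaussian noise of standard deviation `sigma` per channel; the CRLB of
#' `E1`/`E2` is transformed to `T1`/`T2` by the delta method
#' (`T = -tr_ip / ln E`, so `sd(T)/T = sd(E) / (E |ln E|)`).
#'
#' @param block An equal-interval [block_spec()].
#' @param vox A [voxel_params()] with nominal tissue and field values.
#' @param sigma Noise standard deviation per channel, same units as `S0`.
#' @param n_blocks Number of block repetitions.
#' @param S0 Complex signal scale (proton density and receive phase).
#' @return One-row tibble: `cv_t1`, `cv_t2`, `identifiable`.
#' @export
crlb_cv <- function(block, vox, sigma = 0.005, n_blocks = 25, S0 = 1 + 0i) {
  e1 <- exp(-block$tr_ref / vox$T1)
  e2 <- exp(-block$tr_ref / vox$T2)
  theta <- c(Re(S0) * vox$PD, Im(S0) * vox$PD, e1, e2, vox$beta, vox$B1)
  J <- signal_jacobian(theta, block, n_blocks)
  FI <- crossprod(J) / sigma^2
  Finv <- tryCatch(solve(FI), error = function(e) NULL)
  if (is.null(Finv) || any(!is.finite(diag(Finv))) || any(diag(Finv) < 0)) {
    return(tibble::tibble(cv_t1 = Inf, cv_t2 = Inf, identifiable = FALSE))
  }
  tibble::tibble(
    cv_t1 = sqrt(Finv["E1", "E1"]) / (e1 * abs(log(e1))),
    cv_t2 = sqrt(Finv["E2", "E2"]) / (e2 * abs(log(e2))),
    identifiable = TRUE
  )
}

#' Nominal tissues for sequence optimization
#'
#' The factorial of nominal `T1` (800, 1100 ms) and `T2` (50, 200 ms)
#' values spanning most commonly quantified tissues.
#'
#' @return Tibble with columns `T1`, `T2`.
#' @export
design_tissues <- function() {
  tidyr::expand_grid(T1 = c(800, 1100), T2 = c(50, 200))
}

#' CRLB grid search over four-pulse schemes
#'
#' Evaluates `CV_T1`/`CV_T2` for every scheme over a full factorial of
#' flip angles `alpha`, `gamma`, nominal tissues and off-resonance `beta`,
#' then ranks `(scheme, alpha, gamma)` settings by the worst-case
#' (maximum over tissues and `beta`) of the larger of the two CVs. The
#' ranking is independent of `sigma` (CV is proportional to it).
#'
#' @param schemes Tibble from [enumerate_k4_schemes()] (or a subset).
#' @param alpha_grid,gamma_grid Flip-angle grids, degrees. Defaults: 20 to
#'   180 and 10 to 190 in steps of 5.
#' @param tissues Tibble of nominal `T1`, `T2` (ms); default
#'   [design_tissues()].
#' @param beta_grid Off-resonance grid, radians; default 16 points uniform
#'   over `[0, 2 pi)`.
#' @param tr_ip Inter-pulse period, ms.
#' @param n_blocks Block repetitions.
#' @param sigma Noise standard deviation.
#' @param keep_full Also return the per-(tissue, beta) CV table (large).
#' @return List of class `crlb_design`: `aggregate` (tibble: scheme,
#'   alpha, gamma, `cv_t1_max`, `cv_t2_max`, `cv_worst`, sorted), `best`
#'   (top row), and optionally `full`.
#' @export
grid_search <- function(schemes = enumerate_k4_schemes(),
                        alpha_grid = seq(20, 180, by = 5),
                        gamma_grid = seq(10, 190, by = 5),
                        tissues = design_tissues(),
                        beta_grid = seq(0, 2 * pi, length.out = 17)[-17],
                        tr_ip = 30, n_blocks = 25, sigma = 0.005,
                        keep_full = FALSE) {
  stopifnot(nrow(schemes) >= 1, length(alpha_grid) >= 1,
            length(gamma_grid) >= 1, nrow(tissues) >= 1,
            length(beta_grid) >= 1)
  agg <- vector("list", nrow(schemes))
  full <- if (keep_full) vector("list", nrow(schemes)) else NULL
  n_inner <- nrow(tissues) * length(beta_grid)
  for (s in seq_len(nrow(schemes))) {
    cv <- crlb_cv_grid_cpp(schemes$phases[[s]],
                           as.integer(schemes$flip_is_gamma[[s]]),
                           alpha_grid, gamma_grid,
                           as.matrix(tissues[, c("T1", "T2")]),
                           beta_grid, tr_ip, as.integer(n_blocks), sigma)
    grp <- rep(seq_len(length(alpha_grid) * length(gamma_grid)),
               each = n_inner)
    cv1 <- tapply(cv[, 1], grp, max)
    cv2 <- tapply(cv[, 2], grp, max)
    agg[[s]] <- tidyr::expand_grid(scheme = schemes$scheme[s],
                                   alpha = alpha_grid, gamma = gamma_grid)
    agg[[s]]$cv_t1_max <- as.numeric(cv1)
    agg[[s]]$cv_t2_max <- as.numeric(cv2)
    if (keep_full) {
      fl <- tidyr::expand_grid(scheme = schemes$scheme[s],
                               alpha = alpha_grid, gamma = gamma_grid,
                               tissue = seq_len(nrow(tissues)),
                               beta = beta_grid)
      fl$cv_t1 <- cv[, 1]
      fl$cv_t2 <- cv[, 2]
      full[[s]] <- fl
    }
  }
  aggregate <- dplyr::bind_rows(agg)
  aggregate$cv_worst <- pmax(aggregate$cv_t1_max, aggregate$cv_t2_max)
  aggregate <- dplyr::arrange(aggregate, .data$cv_worst)
  structure(
    list(aggregate = aggregate, best = aggregate[1, ],
         full = if (keep_full) dplyr::bind_rows(full) else NULL,
         settings = list(tr_ip = tr_ip, n_blocks = n_blocks, sigma = sigma)),
    class = "crlb_design"
  )
}

#' @export
print.crlb_design <- function(x, ...) {
  cat("<crlb_design> ", nrow(x$aggregate), " (scheme, alpha, gamma) settings\n",
      sep = "")
  cat("  best: scheme ", x$best$scheme, ", alpha = ", x$best$alpha,
      ", gamma = ", x$best$gamma, ", worst-case CV = ",
      format(x$best$cv_worst, digits = 4), "\n", sep = "")
  invisible(x)
}
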