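#' Eigen-parametrization of a block propagator matrix
#'
#' The eigenvalues of a real 3x3 propagator are written as
#' `lambda_1 = rho e^{i phi}`, `lambda_2 = rho e^{-i phi}`, `lambda_3 = eta`,
#' with `eta` real. In the generic dissipative case the pair is complex
#' conjugate (`phi` real, `oscillatory = TRUE`); when all three eigenvalues
#' are real, `phi` is purely imaginary and the returned `phi` holds its
#' imaginary part `psi` with `oscillatory = FALSE` (so that
#' `lambda_{1,2} = rho exp(+/- psi)`). The invariant
#' `rho^2 * eta = det(A)` holds in all branches.
#'
#' When all three eigenvalues are real, `eta` is chosen as the eigenvalue
#' whose (real) eigenvector has the largest longitudinal component, with
#' ties broken by the largest modulus; the remaining two form the
#' "pair". If the remaining two have opposite signs no real `(rho, psi)`
#' exists and the pair is kept as general complex values
#' (`oscillatory = NA`); [putzer_power()] then falls back to the
#' divided-difference evaluation.
#'
#' @param A Real, nonsingular 3x3 matrix.
#' @return An `eigen_triple`: list with `rho`, `phi`, `eta`, `oscillatory`,
#'   `values` (complex eigenvalues, pair first), `vectors`.
#' @export
eigen_parametrize <- function(A) {
  stopifnot(is.matrix(A), all(dim(A) == c(3, 3)), all(is.finite(A)))
  scale <- max(abs(A))
  if (scale == 0 || abs(det(A)) < 1e-14 * scale^3) {
    stop("matrix is singular; eigen-parametrization requires det(A) != 0",
         call. = FALSE)
  }
  ev <- eigen(A)
  lam <- ev$values
  im <- abs(Im(lam))
  tol <- 1e-10 * max(Mod(lam))
  if (any(im > tol)) {
    # one real eigenvalue, one conjugate pair
    i_real <- which.min(im)
    eta <- Re(lam[i_real])
    pair <- lam[-i_real]
    lam1 <- pair[which.max(Im(pair))]
    out <- list(rho = Mod(lam1), phi = abs(Arg(lam1)), eta = eta,
                oscillatory = TRUE,
                values = c(lam1, Conj(lam1), complex(real = eta)),
                vectors = ev$vectors[, c(setdiff(1:3, i_real), i_real)])
  } else {
    lamr <- Re(lam)
    V <- Re(ev$vectors)
    zc <- abs(V[3, ]) / sqrt(colSums(V^2))
    cand <- which(zc > max(zc) - 1e-12)
    i_real <- cand[which.max(abs(lamr[cand]))]
    eta <- lamr[i_real]
    pair <- lamr[-i_real]
    pair <- sort(pair, decreasing = TRUE)
    prod_pair <- pair[1] * pair[2]
    if (prod_pair > 0) {
      s <- sign(pair[1])
      rho <- s * sqrt(prod_pair)
      psi <- log(pair[1] / rho)
      out <- list(rho = rho, phi = psi, eta = eta, oscillatory = FALSE,
                  values = complex(real = c(pair, eta)),
                  vectors = ev$vectors[, c(setdiff(1:3, i_real), i_real)])
    } else {
      out <- list(rho = NA_real_, phi = NA_real_, eta = eta,
                  oscillatory = NA,
                  values = complex(real = c(pair, eta)),
                  vectors = ev$vectors[, c(setdiff(1:3, i_real), i_real)])
    }
  }
  structure(out, class = "eigen_triple")
}

#' @export
print.eigen_triple <- function(x, ...) {
  cat("<eigen_triple>\n")
  if (isTRUE(x$oscillatory)) {
    cat("  rho =", format(x$rho, digits = 8),
        " phi =", format(x$phi, digits = 8), "rad (oscillatory pair)\n")
  } else if (identical(x$oscillatory, FALSE)) {
    cat("  rho =", format(x$rho, digits = 8),
        " psi =", format(x$phi, digits = 8), "(real pair, phi = i*psi)\n")
  } else {
    cat("  real pair of mixed sign:", format(Re(x$values[1:2]), digits = 8), "\n")
  }
  cat("  eta =", format(x$eta, digits = 8), "\n")
  invisible(x)
}

# relative separation of the three eigenvalues; below `tol` the limit
# (confluent) expressions must be used
eig_min_separation <- function(values) {
  s <- max(Mod(values), 1e-300)
  min(Mod(values[1] - values[2]), Mod(values[1] - values[3]),
      Mod(values[2] - values[3])) / s
}

#' Real-valued mode matrices of the propagator
#'
#' Computes the three real 3x3 matrices `M1`, `M2`, `M3` of the real-valued
#' closed form
#' `A^n = rho^n sin(n phi) M1 + rho^n cos(n phi) M2 + eta^n M3`
#' (with `sin`/`cos` replaced by `sinh`/`cosh` of `n psi` when the pair is
#' real). `M3` is the projector onto the real-eigenvalue direction along
#' the pair plane, `M2 = I - M3` exactly, and
#' `M1 = A / (rho sin phi) - (cos phi / sin phi) I
#'       + ((cos phi - eta/rho) / sin phi) M3`.
#'
#' @param A Real, nonsingular 3x3 matrix with a well-separated eigenvalue
#'   pair (relative separation above `degeneracy_tol`).
#' @param degeneracy_tol Relative eigenvalue separation below which the
#'   decomposition is refused (callers fall back to the confluent limit).
#' @return List with `M1`, `M2`, `M3` (real matrices), and the
#'   `eigen_triple`.
#' @export
putzer_matrices <- function(A, degeneracy_tol = 1e-8) {
  et <- eigen_parametrize(A)
  if (is.na(et$oscillatory)) {
    stop("eigenvalue pair of mixed sign: no real mode decomposition",
         call. = FALSE)
  }
  if (eig_min_separation(et$values) < degeneracy_tol) {
    stop("near-degenerate eigenvalues: mode decomposition ill-conditioned",
         call. = FALSE)
  }
  rho <- et$rho; eta <- et$eta
  if (et$oscillatory) {
    cphi <- cos(et$phi); sphi <- sin(et$phi)
  } else {
    cphi <- cosh(et$phi); sphi <- sinh(et$phi)
  }
  D <- rho^2 + eta^2 - 2 * rho * eta * cphi
  I3 <- diag(3)
  M3 <- (A %*% A + rho^2 * I3 - 2 * rho * cphi * A) / D
  M2 <- I3 - M3
  M1 <- A / (rho * sphi) - (cphi / sphi) * I3 +
    ((cphi - eta / rho) / sphi) * M3
  list(M1 = M1, M2 = M2, M3 = M3, eigen = et)
}

# confluent-safe divided differences for f(lambda) = lambda^n
dd1 <- function(a, b, n, tol) {
  if (Mod(a - b) > tol) (a^n - b^n) / (a - b) else n * a^(n - 1)
}
dd2 <- function(a, b, c, n, tol) {
  if (Mod(c - b) > tol) {
    (dd1(a, c, n, tol) - dd1(a, b, n, tol)) / (c - b)
  } else if (Mod(a - b) > tol) {
    # d/db of (a^n - b^n)/(a - b)
    (-n * b^(n - 1) * (a - b) + (a^n - b^n)) / (a - b)^2
  } else {
    if (n < 2) 0 else n * (n - 1) / 2 * a^(n - 2)
  }
}

putzer_power_dd <- function(A, n, values) {
  l1 <- values[1]; l2 <- values[2]; l3 <- values[3]
  tol <- 1e-8 * max(Mod(values), 1e-300)
  I3 <- diag(3)
  B1 <- A - l1 * I3
  res <- l1^n * I3 + dd1(l1, l2, n, tol) * B1 +
    dd2(l1, l2, l3, n, tol) * (B1 %*% (A - l2 * I3))
  Re(res)
}

#' Closed-form matrix power
#'
#' Evaluates `A^n` by the real-valued closed form of [putzer_matrices()]
#' in the generic case; when the eigenvalues are nearly degenerate
#' (relative separation below `degeneracy_tol`) or the real pair has mixed
#' signs, the confluent divided-difference form of the same polynomial
#' identity is used (the documented limit expressions).
#'
#' @param A Real, nonsingular 3x3 matrix.
#' @param n Non-negative integer power.
#' @param degeneracy_tol Relative separation threshold for the limit branch.
#' @return Real 3x3 matrix `A^n`.
#' @export
putzer_power <- function(A, n, degeneracy_tol = 1e-8) {
  stopifnot(n >= 0, n == round(n))
  et <- eigen_parametrize(A)
  if (is.na(et$oscillatory) ||
      eig_min_separation(et$values) < degeneracy_tol) {
    return(putzer_power_dd(A, n, et$values))
  }
  pm <- putzer_matrices(A, degeneracy_tol)
  rho <- et$rho; eta <- et$eta
  if (et$oscillatory) {
    s <- sin(n * et$phi); c <- cos(n * et$phi)
  } else {
    s <- sinh(n * et$phi); c <- cosh(n * et$phi)
  }
  rho^n * (s * pm$M1 + c * pm$M2) + eta^n * pm$M3
}

#' Normal modes of the transient evolution
#'
#' The transient `mu_n = m_n - m_ss` evolves as
#' `mu_n = rho^n sin(n phi) n1 + rho^n cos(n phi) n2 + eta^n n3`
#' with `n_j = M_j mu_0`: two phase-locked damped oscillation directions
#' (`n1`, `n2`) and one exponential-decay direction (`n3`). A mode whose
#' norm falls below `vanish_tol` (relative to `|mu_0|`) is flagged as
#' vanished: the signal then carries no information about the associated
#' eigenvalue.
#'
#' @param A Real 3x3 propagator matrix.
#' @param mu0 Initial transient `m_0 - m_ss`, length-3.
#' @param vanish_tol Relative norm below which a mode counts as vanished.
#' @return List of class `normal_modes`: `n1`, `n2`, `n3`, `M1..M3`,
#'   `vanished` (logical length-3), and the `eigen_triple`.
#' @export
normal_modes <- function(A, mu0, vanish_tol = 1e-10) {
  pm <- putzer_matrices(A)
  mu0 <- as.numeric(mu0)
  n1 <- drop(pm$M1 %*% mu0)
  n2 <- drop(pm$M2 %*% mu0)
  n3 <- drop(pm$M3 %*% mu0)
  ref <- max(sqrt(sum(mu0^2)), 1e-300)
  norms <- c(sqrt(sum(n1^2)), sqrt(sum(n2^2)), sqrt(sum(n3^2)))
  structure(
    list(n1 = n1, n2 = n2, n3 = n3,
         M1 = pm$M1, M2 = pm$M2, M3 = pm$M3,
         norms = norms, vanished = norms < vanish_tol * ref,
         eigen = pm$eigen),
    class = "normal_modes"
  )
}

#' @export
print.normal_modes <- function(x, ...) {
  cat("<normal_modes>  |n1| =", format(x$norms[1], digits = 6),
      " |n2| =", format(x$norms[2], digits = 6),
      " |n3| =", format(x$norms[3], digits = 6), "\n")
  if (any(x$vanished)) {
    cat("  vanished mode(s):", paste0("n", which(x$vanished), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Transient state from the normal-mode expansion
#'
#' @param modes A [normal_modes()] result.
#' @param n Block index (vectorized).
#' @return Matrix with one row per `n`, columns `mux`, `muy`, `muz`.
#' @export
mu_closed_form <- function(modes, n) {
  et <- modes$eigen
  if (isTRUE(et$oscillatory)) {
    s <- sin(n * et$phi); c <- cos(n * et$phi)
  } else {
    s <- sinh(n * et$phi); c <- cosh(n * et$phi)
  }
  out <- outer(et$rho^n * s, modes$n1) + outer(et$rho^n * c, modes$n2) +
    outer(et$eta^n, modes$n3)
  colnames(out) <- c("mux", "muy", "muz")
  out
}

#' Quadrature signal model parameters
#'
#' Parameters of the detected complex transient
#' `s_n = a rho^n e^{i(n phi + delta)} + b eta^n e^{i xi}` obtained from a
#' propagator and an initial state. The detected signal is the transverse
#' projection `mu_x + i mu_y`; the steady-state transverse projection must
#' be added back to model the measured echoes. The expansion in principle
#' also contains a counter-rotating term `q rho^n e^{-i n phi}`; its
#' amplitude is returned as `counter_amplitude` and is zero whenever the
#' oscillating plane projects circularly onto the detection plane.
#'
#' @param A Real 3x3 propagator matrix (oscillatory eigenvalue pair).
#' @param mu0 Initial transient vector.
#' @return List of class `signal_model`: `a`, `delta`, `b`, `xi`, `rho`,
#'   `phi`, `eta`, `counter_amplitude`.
#' @export
signal_model_params <- function(A, mu0) {
  modes <- normal_modes(A, mu0)
  et <- modes$eigen
  if (!isTRUE(et$oscillatory)) {
    stop("signal model requires an oscillatory eigenvalue pair", call. = FALSE)
  }
  c1 <- complex(real = modes$n1[1], imaginary = modes$n1[2])
  c2 <- complex(real = modes$n2[1], imaginary = modes$n2[2])
  c3 <- complex(real = modes$n3[1], imaginary = modes$n3[2])
  p <- (c2 - 1i * c1) / 2    # coefficient of e^{+i n phi}
  q <- (c2 + 1i * c1) / 2    # counter-rotating coefficient
  structure(
    list(a = Mod(p), delta = Arg(p), b = Mod(c3), xi = Arg(c3),
         rho = et$rho, phi = et$phi, eta = et$eta,
         counter = q, counter_amplitude = Mod(q)),
    class = "signal_model"
  )
}

#' Closed-form quadrature signal
#'
#' Evaluates `s_n = a rho^n e^{i(n phi + delta)} + b eta^n e^{i xi}` (plus
#' the counter-rotating term when present in the model object).
#'
#' @param params A [signal_model_params()] result (or list with the same
#'   fields).
#' @param n Block index (vectorized).
#' @param counter Complex counter-rotating coefficient; defaults to the
#'   model's stored coefficient (`0` to evaluate the single-pole form).
#' @return Complex vector of transient signal values.
#' @export
signal_closed_form <- function(params, n, counter = NULL) {
  counter <- counter %||% params$counter %||% 0
  params$a * params$rho^n * exp(1i * (n * params$phi + params$delta)) +
    params$b * params$eta^n * exp(1i * params$xi) +
    counter * params$rho^n * exp(-1i * n * params$phi)
}

#' Continuous interpolant of the discrete evolution
#'
#' The discrete evolution `mu_n = A^n mu_0` embeds in the continuous flow
#' `y(t) = A^{t/TR} mu_0` with `exp(B) = A^{1/TR}`; `y` coincides with
#' `mu_n` at `t = n TR` and traces the smooth spiral between block
#' boundaries. The real matrix power uses the principal branch of the
#' eigenvalue logarithm, which is ambiguous when an eigenvalue lies on the
#' closed negative real axis: that case is an explicit error.
#'
#' @param A Real, nonsingular 3x3 matrix.
#' @param TR Block duration, ms.
#' @param t Time, ms (vectorized).
#' @param mu0 Initial transient vector.
#' @return Matrix with one row per `t`, columns `mux`, `muy`, `muz`.
#' @export
continuous_interpolant <- function(A, TR, t, mu0) {
  ev <- eigen(A)
  lam <- ev$values
  on_branch_cut <- abs(Im(lam)) < 1e-12 * max(Mod(lam)) & Re(lam) <= 0
  if (any(on_branch_cut)) {
    stop("eigenvalue on the negative real axis: matrix power branch is ",
         "ambiguous", call. = FALSE)
  }
  Vinv_mu <- solve(ev$vectors, as.complex(as.numeric(mu0)))
  out <- t(vapply(t, function(tt) {
    y <- ev$vectors %*% (exp((tt / TR) * log(lam)) * Vinv_mu)
    if (max(abs(Im(y))) > 1e-8 * max(abs(y), 1)) {
      stop("continuous interpolant is not real-valued", call. = FALSE)
    }
    Re(drop(y))
  }, numeric(3)))
  colnames(out) <- c("mux", "muy", "muz")
  out
}
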