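#' Default vial layout
#'
#' Twelve gel vials with relaxation times spanning the clinically common
#' range (T1 300-1100 ms, T2 50-200 ms), arranged on a ring. A synthetic
#' stand-in for a standardized relaxometry vial set; the values are
#' package defaults, not measured gel values.
#'
#' @param n_grid Grid side length the layout is scaled to.
#' @return Tibble: `vial`, `T1`, `T2`, `PD`, `cx`, `cy`, `r`.
#' @export
vial_layout <- function(n_grid = 64) {
  T1 <- c(300, 380, 460, 540, 620, 700, 780, 860, 940, 1020, 1060, 1100)
  T2 <- c(50, 56, 64, 72, 82, 92, 104, 118, 132, 150, 170, 200)
  ang <- 2 * pi * (seq_len(12) - 1) / 12
  ring <- 0.36 * n_grid
  tibble::tibble(
    vial = seq_len(12), T1 = T1, T2 = T2, PD = 1,
    cx = (n_grid + 1) / 2 + ring * cos(ang),
    cy = (n_grid + 1) / 2 + ring * sin(ang),
    r = 0.075 * n_grid
  )
}

#' Gray/white-matter tissue presets
#'
#' Literature reference values for gray and white matter at 1.5 T:
#' T1 1048 / 561 ms, T2 94 / 63 ms.
#'
#' @return Tibble with `tissue`, `T1`, `T2`, `PD`.
#' @export
tissue_presets <- function() {
  tibble::tibble(
    tissue = c("GM", "WM"),
    T1 = c(1048, 561), T2 = c(94, 63), PD = c(0.85, 0.7)
  )
}

#' Digital vial phantom with smooth imperfection fields
#'
#' Builds a 2-D digital phantom: circular vials of constant `(T1, T2, PD)`
#' on a zero-PD background, a smooth static-field offset map (linear ramp
#' across the image, peak amplitude `b0_amp_hz`), and a radial transmit
#' bowl running from `b1_range[2]` at the centre to `b1_range[1]` at the
#' image corner radius.
#'
#' @param layout Vial table as from [vial_layout()]; vials must not
#'   overlap.
#' @param n_grid Image side length, voxels.
#' @param b0_amp_hz Peak static-field offset, Hz (ramp spans
#'   `[-b0_amp_hz, b0_amp_hz]`); 0 disables.
#' @param b1_range Transmit scale range spanned across the image (min at
#'   the point farthest from the bowl centre, max at the centre). The
#'   bowl is deliberately off-centre so the field varies within any vial
#'   ring.
#' @return Tibble of class `mp_phantom`: one row per voxel with `x`, `y`,
#'   `vial` (0 = background), `T1`, `T2`, `PD`, `B0_hz`, `B1`, `mask`.
#' @export
make_vial_phantom <- function(layout = vial_layout(), n_grid = 64,
                              b0_amp_hz = 15, b1_range = c(0.8, 1.2)) {
  d2 <- outer(layout$cx, layout$cx, "-")^2 + outer(layout$cy, layout$cy, "-")^2
  rr <- outer(layout$r, layout$r, "+")^2
  if (any(d2[upper.tri(d2)] < rr[upper.tri(rr)])) {
    stop("vials overlap", call. = FALSE)
  }
  ph <- tidyr::expand_grid(x = seq_len(n_grid), y = seq_len(n_grid))
  vial <- integer(nrow(ph))
  for (v in seq_len(nrow(layout))) {
    inside <- (ph$x - layout$cx[v])^2 + (ph$y - layout$cy[v])^2 <=
      layout$r[v]^2
    vial[inside] <- layout$vial[v]
  }
  ph$vial <- vial
  idx <- match(ph$vial, layout$vial)
  ph$T1 <- ifelse(is.na(idx), NA_real_, layout$T1[idx])
  ph$T2 <- ifelse(is.na(idx), NA_real_, layout$T2[idx])
  ph$PD <- ifelse(is.na(idx), 0, layout$PD[idx])
  ph$B0_hz <- b0_amp_hz * (2 * (ph$x - 1) / (n_grid - 1) - 1)
  d2 <- (ph$x - 0.30 * n_grid)^2 + (ph$y - 0.35 * n_grid)^2
  ph$B1 <- b1_range[2] -
    (b1_range[2] - b1_range[1]) * (d2 - min(d2)) / (max(d2) - min(d2))
  ph$mask <- ph$PD > 0
  class(ph) <- c("mp_phantom", class(ph))
  attr(ph, "n_grid") <- n_grid
  attr(ph, "layout") <- layout
  ph
}

#' Two-compartment tissue phantom
#'
#' Concentric disc (gray matter ring around a white-matter core) phantom
#' from the [tissue_presets()] values, mainly for contrast-synthesis
#' demonstrations.
#'
#' @param n_grid Image side length.
#' @return An `mp_phantom` tibble (same columns as [make_vial_phantom()]).
#' @export
make_tissue_phantom <- function(n_grid = 64) {
  pre <- tissue_presets()
  ph <- tidyr::expand_grid(x = seq_len(n_grid), y = seq_len(n_grid))
  c0 <- (n_grid + 1) / 2
  r <- sqrt((ph$x - c0)^2 + (ph$y - c0)^2)
  ph$vial <- ifelse(r <= 0.2 * n_grid, 2L, ifelse(r <= 0.4 * n_grid, 1L, 0L))
  idx <- match(ph$vial, c(1L, 2L))
  ph$T1 <- pre$T1[idx]
  ph$T2 <- pre$T2[idx]
  ph$PD <- ifelse(is.na(idx), 0, pre$PD[idx])
  ph$B0_hz <- 0
  ph$B1 <- 1
  ph$mask <- ph$PD > 0
  class(ph) <- c("mp_phantom", class(ph))
  attr(ph, "n_grid") <- n_grid
  ph
}

# run `code` under a fixed RNG state without disturbing the caller's
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed %% 2147483647))
  force(code)
}

# deterministic sub-seed derivation, kept below 2^31
derive_seed <- function(seed, salt) {
  as.integer((as.numeric(seed) * 48271 + salt) %% 2147483587)
}

#' Simulate a transient echo-train dataset
#'
#' Per-voxel complex echo trains for a phantom under a repeated-block
#' acquisition, starting from thermal equilibrium, with additive i.i.d.
#' circular complex Gaussian noise of standard deviation `sigma` per
#' channel. Specify either `sigma` directly or `snr`, in which case
#' `sigma = max |noiseless signal| / snr` (peak signal-to-noise).
#'
#' @param phantom An `mp_phantom` tibble.
#' @param block Acquisition block; default the four-pulse multi-phase
#'   scheme `alpha = 30`, `gamma = 175`, 30 ms inter-pulse period.
#' @param n_blocks Block repetitions (default 25, i.e. 100 echoes).
#' @param sigma Noise standard deviation per channel (absolute).
#' @param snr Peak signal-to-noise ratio (used when `sigma` is `NULL`).
#' @param seed Integer seed; fixed seed gives identical datasets.
#' @return An `mp_dataset`: list with `echoes` (complex `n_echo` x
#'   `n_voxel` matrix, voxels in phantom row order), `phantom`, `block`,
#'   `n_blocks`, `sigma`, `seed`.
#' @export
simulate_dataset <- function(phantom, block = scheme_block("mp"),
                             n_blocks = 25, sigma = NULL, snr = NULL,
                             seed = 1) {
  stopifnot(inherits(phantom, "mp_phantom"))
  pt <- block_pulse_table(block)
  tr <- block$tr_ref
  n_echo <- n_blocks * nrow(pt)
  n_vox <- nrow(phantom)
  echoes <- matrix(0 + 0i, n_echo, n_vox)
  beta <- 2 * pi * phantom$B0_hz * tr * 1e-3
  live <- which(phantom$mask)
  for (i in live) {
    echoes[, i] <- sim_train_cpp(
      pt$flip, pt$phase, as.integer(n_blocks),
      exp(-tr / phantom$T1[i]), exp(-tr / phantom$T2[i]), phantom$PD[i],
      beta[i], phantom$B1[i], c(0, 0, phantom$PD[i])
    )
  }
  if (is.null(sigma)) {
    sigma <- if (is.null(snr)) 0 else max(Mod(echoes)) / snr
  }
  if (sigma > 0) {
    noise <- with_seed(seed, {
      complex(real = stats::rnorm(n_echo * n_vox, sd = sigma),
              imaginary = stats::rnorm(n_echo * n_vox, sd = sigma))
    })
    echoes <- echoes + matrix(noise, n_echo, n_vox)
  }
  structure(
    list(echoes = echoes, phantom = phantom, block = block,
         n_blocks = n_blocks, sigma = sigma, seed = seed, tr_ip = tr),
    class = "mp_dataset"
  )
}

#' @export
print.mp_dataset <- function(x, ...) {
  cat("<mp_dataset> ", nrow(x$echoes), " echoes x ", ncol(x$echoes),
      " voxels, sigma = ", format(x$sigma, digits = 4),
      ", seed = ", x$seed, "\n", sep = "")
  invisible(x)
}

# equal-probability quantile midpoints of a truncated (+/- 3 sd) Gaussian
dispersion_offsets <- function(spread, n_iso) {
  if (spread == 0 || n_iso == 1) return(rep(0, n_iso))
  p <- (seq_len(n_iso) - 0.5) / n_iso
  lim <- stats::pnorm(c(-3, 3))
  stats::qnorm(lim[1] + p * (lim[2] - lim[1])) * spread
}

#' Intra-voxel off-resonance dispersion
#'
#' Average echo train of `n_iso` isochromats whose off-resonance phases
#' are spread around `vox$beta` with a truncated Gaussian profile
#' (standard deviation `spread` radians per inter-pulse period, truncated
#' at three standard deviations, sampled at deterministic
#' equal-probability quantile midpoints). Fitting the averaged train with
#' the single-species model quantifies the dispersion-induced T1/T2 bias.
#'
#' @param vox A [voxel_params()] (its `beta` is the dispersion centre).
#' @param block Acquisition block.
#' @param n_blocks Block repetitions.
#' @param spread Dispersion width, radians per inter-pulse period.
#' @param n_iso Number of isochromats (>= 1).
#' @return Complex echo-train vector (average over isochromats).
#' @export
simulate_dispersion <- function(vox, block = scheme_block("mp"),
                                n_blocks = 25, spread = 0, n_iso = 33) {
  stopifnot(n_iso >= 1)
  offs <- dispersion_offsets(spread, n_iso)
  trains <- vapply(offs, function(db) {
    v <- voxel_params(vox$T1, vox$T2, vox$PD, beta = vox$beta + db,
                      B1 = vox$B1)
    sim_train(block, v, n_blocks)
  }, complex(n_blocks * length(block_pulse_table(block)$flip)))
  rowMeans(trains)
}

#' Effective T2* under off-resonance dispersion
#'
#' Mono-exponential decay time fitted to the magnitude of the dispersed
#' free-induction decay `f(t) = exp(-t/T2) |mean_k exp(i beta_k t/tr)|`
#' sampled at multiples of the inter-pulse period, using the initial
#' strictly decaying portion. This is the decay a gradient-echo
#' experiment would see for the same isochromat ensemble.
#'
#' @inheritParams simulate_dispersion
#' @param tr_ip Inter-pulse period, ms.
#' @param n_samples FID samples used.
#' @return T2* estimate, ms.
#' @export
dispersion_t2star <- function(vox, spread, n_iso = 33, tr_ip = 30,
                              n_samples = 60) {
  offs <- dispersion_offsets(spread, n_iso)
  n <- seq_len(n_samples)
  f <- exp(-n * tr_ip / vox$T2) *
    Mod(vapply(n, function(k) mean(exp(1i * offs * k)), complex(1)))
  keep <- seq_len(max(which(cumprod(c(TRUE, diff(f) < 0)) == 1)))
  keep <- keep[f[keep] > 1e-6]
  if (length(keep) < 2) return(tr_ip / 2)
  fit <- stats::lm(log(f[keep]) ~ n[keep])
  -tr_ip / unname(stats::coef(fit)[2])
}
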