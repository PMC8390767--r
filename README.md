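# mpbnssfp

Transient-state multiparametric MRI mapping with composite balanced
propagators.

`mpbnssfp` is for MR physicists and methods researchers who want to
simulate, design and fit repeated-block balanced sequences read out
during the transient response. One short echo train per voxel yields
simultaneous maps of T1, T2, proton density, the static-field offset
(B0), the transmit scale (B1) and the per-block dissipation (HO map) —
no dictionary, no separate calibration scans — and weighted contrasts
(T1w, T2w, FLAIR) can be synthesized from the fitted maps.

## The model

One acquisition block (RF pulses interleaved with free precession over a
repetition period T_R) acts on the magnetization as an affine map

    m_{n+1} = A m_n + c,      m_ss = (I − A)^{-1} c,

so the transient mu_n = m_n − m_ss evolves as mu_n = A^n mu_0. The
eigenvalues of the block propagator A are rho·e^{±i phi} and eta, and A^n
has the exact real-valued closed form

    A^n = rho^n sin(n phi) M1 + rho^n cos(n phi) M2 + eta^n M3,

two phase-locked damped oscillations plus one exponential decay along the
normal modes n_j = M_j mu_0. The determinant rho²·eta =
exp(−2 T_R/T2)·exp(−T_R/T1) is the per-block dissipation (HO). The
detected quadrature signal s_n = m_x + i m_y is fitted voxelwise with

    theta = argmin_theta | S − Bloch(theta) |²,
    theta = [Re S0, Im S0, E1, E2, beta, B1],

E1 = exp(−TR/T1), E2 = exp(−TR/T2) per inter-pulse period, beta the
off-resonance phase per period, using 5 bounded Levenberg–Marquardt
starts screened from 1000 candidates with S0 solved in closed form.

The default acquisition is the four-pulse multi-phase block
alpha_x − gamma_y − alpha_y − gamma_x (alpha = 30°, gamma = 175°, 30 ms
inter-pulse period, four readouts per block, 25 repeats = 100 echoes),
whose oscillation frequency is nearly independent of beta — the
banding-suppression property — and which keeps all three normal modes
alive at every off-resonance.

## Worked example

```r
library(mpbnssfp)

blk <- scheme_block("mp", alpha = 30, gamma = 175, tr_ip = 30)
vox <- voxel_params(T1 = 800, T2 = 90, PD = 1, beta = 0.6, B1 = 1.05)

compose_block(blk, vox)
#> <propagator> 3x3 affine block map
#>   det(A) = 0.0598049607
#>   m_ss   = -0.00156986  0.00180795  0.00201641

eigen_parametrize(compose_block(blk, vox)$matrix)
#> <eigen_triple>
#>   rho = 0.28630935  phi = 2.9851486 rad (oscillatory pair)
#>   eta = 0.72956863

# simulate a noisy 100-echo train and fit it back
set.seed(1)
S <- sim_train(blk, vox, n_blocks = 25) +
  complex(real = rnorm(100, sd = 0.004), imaginary = rnorm(100, sd = 0.004))
fit <- fit_train(S, blk, n_blocks = 25, config = fit_config(seed = 1))
tidy(fit)
#> # A tibble: 10 x 2
#>    term   estimate
#>  1 ReS0    0.999
#>  2 ImS0   -0.00470
#>  3 E1      0.963
#>  4 E2      0.716
#>  5 beta    0.607
#>  6 B1      1.05
#>  7 T1    794.
#>  8 T2     89.8
#>  9 PD      0.999
#> 10 B0_hz   3.22
```

`det(A) = 0.0598` is the HO dissipation of the 120 ms block
(`ho_value(vox, 120)` gives the same number without composing anything —
rotations are volume-preserving). The fit recovers T1 = 794 ms and
T2 = 89.8 ms from a single train at roughly 1% noise, together with the
off-resonance (beta 0.607 rad -> 3.2 Hz) and the transmit scale 1.05.

Phantom-scale work goes through the tabular pipeline:

```r
ph   <- make_vial_phantom()                      # 12 vials, B0/B1 fields
ds   <- simulate_dataset(ph, snr = 50, seed = 1) # 100 echoes per voxel
maps <- fit_dataset(ds) |> assemble_maps()       # one row per voxel
plot_map(maps, "T1")
synthesize_contrast(maps, TE = 120, TR = 4500)   # synthetic T2w
```

A thin command-line front end wraps the same functions
(`inst/cli/mpbnssfp.R`, subcommands `simulate | eigmap | design | fit |
synth`), writing NIfTI maps, CSV tables and JSON run manifests.

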