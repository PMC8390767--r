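---
title: "Transient-state multiparametric mapping with composite balanced propagators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transient-state multiparametric mapping with composite balanced propagators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpbnssfp)
```

## The model

A repeated acquisition block of a balanced MRI sequence — RF excitations
interleaved with free-precession intervals — acts on the magnetization
vector $m \in \mathbb{R}^3$ as an affine map: one block repetition gives

$$m_{n+1} = A\,m_n + c, \qquad m_{ss} = (I - A)^{-1} c,$$

where $A$ is the ordered product of rotation operators (RF pulses, scaled
by the transmit field $B_1$; off-resonance precession by $\beta$ radians
per inter-pulse period) and relaxation operators
$E(\tau) = \mathrm{diag}(e^{-\tau/T_2}, e^{-\tau/T_2}, e^{-\tau/T_1})$
with longitudinal recovery towards $(0, 0, \mathrm{PD})$. The transient
$\mu_n = m_n - m_{ss}$ obeys $\mu_n = A^n \mu_0$.

Because every physical block dissipates, the eigenvalues of $A$ can be
written $\rho e^{\pm i\varphi}$ and $\eta$, and $A^n$ has an exact
real-valued closed form built from three mode matrices:

$$A^n = \rho^n \sin(n\varphi)\, M_1 + \rho^n \cos(n\varphi)\, M_2
       + \eta^n M_3,$$

with $M_3$ the spectral projector onto the real-eigenvalue direction,
$M_2 = I - M_3$, and
$M_1 = A/(\rho\sin\varphi) - (\cos\varphi/\sin\varphi) I +
\big((\cos\varphi - \eta/\rho)/\sin\varphi\big) M_3$.
(Deriving the mode matrices from the three-eigenvalue polynomial identity
shows that the $M_3$ coefficient in $M_1$ carries the $1/\sin\varphi$
factor; without it the decomposition fails already for a pure rotation
about z, which is how the package's unit tests pin the formula.)
The transient therefore evolves as two phase-locked damped oscillations
plus one exponential decay along the normal modes $n_j = M_j\,\mu_0$, and
$\rho^2\eta = \det A = e^{-2 T_R/T_2} e^{-T_R/T_1}$ is the total
dissipation per block — reconstructed voxelwise as the HO map.

Degenerate eigenvalues are handled by the confluent limit of the same
polynomial identity (divided differences with l'Hôpital limits), which the
package uses whenever the relative eigenvalue separation falls below
`1e-8`, and also when the "pair" is real with mixed signs (possible for
flip angles at 180 degrees), where no real $(\rho, \varphi)$ exists.

### The detected signal

Quadrature detection projects $m_n$ onto the transverse plane,
$s_n = m_{n,x} + i\,m_{n,y}$. Expanding the normal modes in complex
exponentials gives

$$s_n - s_{ss} = a\rho^n e^{i(n\varphi + \delta)}
  + q\,\rho^n e^{-i n\varphi} + b\eta^n e^{i\xi}.$$

The counter-rotating coefficient $q$ vanishes only when the oscillation
plane projects circularly onto the detection plane; exactly on resonance
the projection degenerates to a line and $|q| = a$. The package keeps $q$
(`signal_model_params()` returns it; `signal_closed_form()` includes it by
default), making the closed-form reconstruction of the recursion exact
for every block index.

### Information content and sequence design

For a single-excitation block at exact on-resonance ($\beta = 0$) the
equilibrium-start transient lies entirely in the oscillating-mode plane:
$n_3 = M_3 \mu_0 = 0$, the derivative of the transient along the $\eta$
eigen-direction, $n\,\eta^{n-1} M_3\mu_0$, vanishes identically, and the
train carries no information about $\eta$. (In the fitting
parametrization $(E_1, E_2, \beta, B_1)$ the Fisher matrix remains
regular, because on resonance $\eta = E_2$ is not an independent
coordinate: $E_2$ stays visible through $\rho^2 = E_1 E_2$. The
information loss is a statement about the eigenvalue itself.) Since
$\beta$ cannot be controlled across a field of view, at least two
excitations with distinct transverse phases are needed to keep all three
modes alive for every $\beta$ — the motivation for composite blocks.

`eigenvalue_map()` and `topology_check()` inspect a scheme as a map from
the $(T_2, \beta)$ species plane to the eigenvalue plane. A usable scheme
must be single-valued and proximity-preserving there. Two species related
by $\beta \to -\beta$ always share eigenvalues (conjugate pairs of a real
matrix), so that inherent fold is not counted as a collision — the signal
phase still separates the pair, which is why the fitted $B_0$ map recovers
the sign of $\beta$. The two-pulse x/y scheme genuinely folds $\beta$ with
$\beta + \pi$ and is flagged; the four-pulse multi-phase block
$\alpha_x\,\gamma_y\,\alpha_y\,\gamma_x$ passes, and its oscillation
frequency $\varphi$ is nearly independent of $\beta$
(`banding_metric()`), which is the mechanism that suppresses banding
waves during the transient.

## Tunable parameters

* **Block geometry** — `scheme_block()` defaults: $\alpha = 30^\circ$,
  $\gamma = 175^\circ$, inter-pulse period `tr_ip = 30` ms, four readouts
  per block (one at the end of each interval), 25 block repetitions, i.e.
  100 complex echoes per voxel starting from thermal equilibrium.
* **Off-resonance** — $\beta$ in radians per inter-pulse period;
  $B_0[\mathrm{Hz}] = \beta / (2\pi\,\mathrm{tr\_ip}\,[s])$.
* **Fit bounds** (`fit_config()`) — $E_1 \in [0.9, 1]$,
  $E_2 \in [0.3, 1]$, $\beta \in [-\pi, \pi]$, $B_1 \in [0.5, 1.5]$;
  1000 screened candidates, 5 refined starts. The $E_1$ lower bound
  censors $T_1 \lesssim 285$ ms at a 30 ms inter-pulse period; the bound
  is exposed for short-$T_1$ work.
* **CRLB search** (`grid_search()`) — $\alpha \in [20^\circ, 180^\circ]$,
  $\gamma \in [10^\circ, 190^\circ]$ in $5^\circ$ steps, nominal tissues
  $T_1 \in \{800, 1100\}$ ms $\times$ $T_2 \in \{50, 200\}$ ms, and a
  16-point $\beta$ grid (a package default; CV rankings are independent
  of the noise scale $\sigma$).

## Design choices

* **RF pulses** are ideal (zero-duration) rotations about a transverse
  axis at azimuth `phase` measured from x, realized as
  $R_z(\phi) R_x(\theta) R_z(-\phi)$, with $B_1$ a pure scalar multiplier
  of every flip angle. Slice-profile integration is deliberately not
  modelled; the fitting model uses the same hard pulses, so simulation
  and estimation are self-consistent.
* **Off-resonance placement** — $\beta$ accrues uniformly over
  free-precession time, split proportionally to each interval and
  interleaved with relaxation; the two operators commute (both are
  block-diagonal in the transverse plane), so the ordering is immaterial
  and is asserted in the tests.
* **Readout convention** — the echo is recorded at the end of each
  free-precession interval. For a balanced block the mid-interval echo
  differs only by a fixed half-interval phase/decay, which the complex
  scale $S_0$ and $\beta$ absorb.
* **Real-eigenvalue selection** when all three eigenvalues are real:
  the eigenvalue whose eigenvector has the largest longitudinal
  component, ties broken by modulus — the longitudinal-like direction is
  the natural continuation of the $\eta$ branch.
* **Four-pulse scheme enumeration** — the 16 x/y axis assignments are
  deduplicated under reversal of the pulse order within the block (the
  same pulse set traversed backwards), leaving exactly ten unique
  schemes; the count is unit-tested.
* **"Best compromise" aggregation** — `grid_search()` ranks settings by
  the worst-case of $\mathrm{CV}_{T_1}$ and $\mathrm{CV}_{T_2}$ over
  tissues and $\beta$. With ideal hard pulses this raw ranking favors
  large-$\alpha$/small-$\gamma$ settings; restricting to $B_0$-robust
  settings (per-tissue CV max/min ratio over $\beta$ below 1.5) brings
  the small-$\alpha$, $\gamma \approx 180^\circ$ refocusing family —
  including $\alpha = 30^\circ, \gamma = 175^\circ$ — to the top of the
  ranking. Both views are computable from the `keep_full = TRUE` output,
  and the acceptance suite records both quantiles.
* **Optimizer** — bounded Levenberg-Marquardt least squares
  (`minpack.lm::nls.lm`) on the real/imaginary-stacked residual; the
  multi-start contract (best 5 of 1000 screened candidates, lowest final
  cost wins) is what matters, not the specific trust-region variant.
  The candidate screen solves the complex scale $S_0$ in closed form by
  linear least squares against each unit-scale model train; in
  `fit_dataset()` the candidate trains are computed once and shared by
  all voxels (they do not depend on the data), so results are independent
  of traversal order.

## The synthetic-data generator

`make_vial_phantom()` builds a 64 x 64 image with twelve circular vials on
a ring, $T_1 \in [300, 1100]$ ms and $T_2 \in [50, 200]$ ms spanning the
commonly quantified range, unit proton density, a linear static-field
ramp of $\pm 15$ Hz across the image, and a smooth transmit bowl spanning
$B_1 \in [0.8, 1.2]$. The bowl is deliberately off-centre: a bowl centred
on the vial ring would be nearly constant over the mask, leaving the
$B_1$ recovery check without dynamic range. `simulate_dataset()` adds
i.i.d. circular complex Gaussian noise per channel; `snr = 50` sets
$\sigma$ to the peak noiseless magnitude divided by 50. Fixed seeds give
byte-identical datasets.

Intra-voxel static-field dispersion (`simulate_dispersion()`) averages
isochromats whose $\beta$ offsets sample a truncated ($\pm 3\sigma$)
Gaussian at deterministic equal-probability quantile midpoints, so the
sweep of the dispersion-bias study is smooth in the width parameter.
`dispersion_t2star()` provides the matched mono-exponential $T_2^*$ proxy
from the dispersed free-induction decay.

What the generator deliberately does not emulate: k-space sampling and
reconstruction (spiral trajectories, gridding artifacts), coil
sensitivities, motion, drift, slice profiles, multi-compartment
relaxation, magnetization transfer and diffusion. Passing the recovery
tests therefore demonstrates the estimator's correctness and conditioning
under the model's own assumptions, not robustness to everything a scanner
adds; the dispersion study probes exactly one of those violations
(intra-voxel $B_0$ spread) and shows a small, monotone bias with fitted
$T_2$ remaining well above $T_2^*$.

## Numerical choices

* Eigen-degeneracy tolerance `1e-8` (relative separation) switches the
  closed-form power to the confluent branch; the branch is exercised in
  tests with $|\varphi| < 10^{-6}$ and with triple-degenerate pure
  relaxation.
* Jacobians for the Fisher information use central differences with
  relative step `1e-6`; the $S_0$ columns are exact by linearity.
  $\mathrm{CV}_{T} = \mathrm{sd}(E)/(E\,|\ln E|)$ by the delta method.
* The continuous interpolant $y(t) = A^{t/T_R}\mu_0$ uses the principal
  eigenvalue logarithm and refuses matrices with eigenvalues on the
  closed negative real axis rather than silently choosing a branch.
* Estimates at the $E = 1$ bound are reported as censored (`NA` with a
  `censored` flag) instead of an infinite relaxation time.

## Problem sizes

The shipped tests fit the full 64 x 64 twelve-vial phantom (about 820
in-mask voxels, 100 echoes each) in well under a minute, run the complete
CRLB factorial (10 schemes x 33 x 37 flip-angle pairs x 4 tissues x 16
$\beta$ values, ~781k Fisher matrices) in tens of seconds via the
compiled kernel, and use 200 Monte-Carlo replicates for the
CRLB-consistency check. These sizes were chosen to keep a full run
interactive on a single core while leaving the statistical checks
well-powered.

## Known limitations

* $T_1$ values below the $E_1$ bound are censored by construction.
* The single-species model is the estimator's assumption, not a fact
  about tissue; dispersion, exchange and magnetization transfer bias
  $T_1$ in real data in ways the generator only partially emulates.
* The eigenvalue-plane diagnostics use the nominal $B_1 = 1$; strong
  transmit inhomogeneity shifts the effective flip angles and hence the
  topology margins.
* `grid_search()` ranks by CV only; SAR, peak RF power and slice-profile
  feasibility — practical drivers of flip-angle choices on scanners —
  are out of scope.
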