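---
title: "Two-field active nematics: model, numerics, and measurement protocol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-field active nematics: model, numerics, and measurement protocol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(activenematic)
```

## The model

Confluent epithelial monolayers behave, at the tissue scale, like active
nematic fluids. The usual continuum description carries a single orientational
order parameter; this package implements a two-field extension in which the
orientation of the cell body and the orientation of the cell-generated
contractile stress are distinct degrees of freedom:

* $Q^n = S^n(\mathbf{n}\mathbf{n} - I/2)$ — the **shape tensor**, whose
  director $\mathbf{n}$ is the long axis of the cell and whose magnitude
  $S^n$ measures local shape alignment;
* $Q^m = S^m(\mathbf{m}\mathbf{m} - I/2)$ — the **stress tensor order
  parameter**, whose director $\mathbf{m}$ is the principal axis of
  contractile stress (experimentally, the positive principal axis of the
  monolayer-stress-microscopy stress tensor).

The misalignment angle $\theta = \cos^{-1}(\mathbf{n}\cdot\mathbf{m}) \in
[0^\circ, 90^\circ]$ classifies tissue locally: $\theta > 45^\circ$ is
**extensile** (the cell pulls along its short axis), $\theta \le 45^\circ$
**contractile**. The tie at exactly $45^\circ$ is classified contractile
(the extensile class is defined by a strict inequality).

Both tensors relax in a shared free-energy density

$$f = \tfrac{C}{2}(1 - 3\,Q^n\!:\!Q^n)^2 + \tfrac{C}{2}(1 - 3\,Q^m\!:\!Q^m)^2
    + \tfrac{K_n}{2}|\nabla Q^n|^2 + \tfrac{K_m}{2}|\nabla Q^m|^2
    + \tfrac{J}{2}(1 - 3\,Q^n\!:\!Q^m)^2 ,$$

whose $C$ terms select ordered states with $S = \sqrt{2/3}$ (note
$Q\!:\!Q = S^2/2$ in two dimensions), whose elastic constants penalise
gradients — $K_n > K_m$ encodes the experimental observation that shape
orientations are correlated over longer distances than stress
orientations — and whose $J$ term relaxes the misalignment. The dynamics is
co-rotational and relaxational,

$$(\partial_t + \mathbf{u}\cdot\nabla)\,Q^x =
   -\Omega\,Q^x + Q^x\,\Omega + \gamma H^x , \qquad
   H^x = -\Big(\frac{\delta f}{\delta Q^x}
   - \tfrac{I}{2}\mathrm{Tr}\frac{\delta f}{\delta Q^x}\Big), \quad
   x \in \{n, m\},$$

with the flow-tumbling parameter set to zero: only the vorticity
$\Omega$ rotates the directors, and it rotates both at the same local
angular velocity. Misalignment can therefore only be *generated* by the
different elastic responses of the two fields, and is *erased* by the $J$
coupling — the central competition of the model.

The flow obeys the momentum balance $\rho(\partial_t +
\mathbf{u}\cdot\nabla)\mathbf{u} = \nabla\cdot\Pi$ with the active stress
$\Pi_{\text{act}} = -\zeta Q^m$; $\zeta < 0$ is contractile (the positive
principal axis of $\Pi_{\text{act}}$ lies along $\mathbf{m}$). The passive
stress is viscous (plus the ideal lattice-gas pressure); the elastic
(Ericksen and antisymmetric director-torque) back-stress of both tensors is
available as an option (`simulate_monolayer(backstress = TRUE)`) but is off
by default — it changed no headline statistic by more than a percentage
point in our sensitivity runs, and the minimal closure is easier to reason
about.

## Parameters

`model_params("mdck")` is the active, turbulent parameter set (in
lattice-Boltzmann units): $\gamma = 0.4$, $K_m = 0.005$, $C = 10^{-3}/3$,
$\zeta = -0.03$, $K_n = 0.065$, $J = 0.0008$, $\rho = 40$, $\eta = 20/3$.
`model_params("lp9")` is the passive island variant: $K_m = 0.02$,
$K_n = 0.01$, $\zeta = 0$, with the exterior bulk scale $C' = 0.003$ and
island radius $R = 80$. The unit calibration — 3 µm per lattice unit and
0.1 min per time step — lives in `run_config()`, not in the operations, so
all physical-unit interfaces (5.2 µm interface half-width, 312 µm averaging
disc, 15-min frame cadence) convert through the configuration.

With $\rho = 40$ and $\eta = 20/3$ the kinematic viscosity is $\nu = 1/6$,
i.e. a BGK relaxation time $\tau = 1$ (`lb_tau()`), and the grid Reynolds
number stays below $0.1$: flows are inertially negligible at the lattice
scale.

### A note on the alignment coupling

The quartic alignment term above is soft near perfect alignment (its torque
vanishes cubically in the misalignment when both fields sit at the ordered
magnitude), and at the default parameters its effective misalignment
relaxation time in the turbulent state is a few minutes. The package also
provides `model_params(coupling = "harmonic")`, which substitutes the
harmonic alignment $\tfrac{J}{2}|Q^n - Q^m|^2$; its relaxation time is
exactly $1/(2\gamma J)$ (≈ 16 min at the defaults), matching the
realignment timescale reported for this class of experiments. Both forms
pass the same functional-derivative and free-energy-descent checks; the
quartic form is the default because it is the literal free-energy
expression. The choice matters quantitatively: see *Sensitivity* below.

## Numerics

* **Storage.** Only $(Q_{xx}, Q_{xy})$ are stored; $Q_{yy} = -Q_{xx}$ is
  implied, so symmetry and tracelessness are structural invariants, exact
  to the last bit.
* **Hybrid scheme.** D2Q9 lattice Boltzmann with BGK collision and Guo
  forcing for the momentum equation (the body force is the divergence of
  the active stress, central differences); explicit Euler
  ($\Delta t = 1$ step) with central-difference advection and vorticity for
  the tensor dynamics. Guo forcing includes the half-force correction in
  the macroscopic velocity; the forced steady Stokes response was verified
  against the exact solution to seven digits.
* **Discrete variational consistency.** The elastic energy is discretized
  with compact one-sided differences, whose exact discrete functional
  derivative is the 5-point Laplacian used in $H$. (The more obvious
  central-difference energy has a *wide* 2-step Laplacian as its exact
  adjoint, which decouples the even and odd sublattices; with the compact
  form, the analytic molecular field matches a numerical derivative of the
  discrete free energy to better than $10^{-5}$ on random states, and free
  energy descends monotonically under relaxation.)
* **Vorticity convention.** $\Omega_{xy} = (\partial_x u_y - \partial_y
  u_x)/2$: a rigid rotation $\mathbf{u} = w(-y, x)$ gives
  $\Omega_{xy} = w$ and both directors rotate at angular velocity $w$.
* **Stability.** The scheme is stable at the default parameters
  ($\gamma K_n = 0.026$ per step, well under the diffusive limit; the CFL
  guard aborts if $|\mathbf{u}|\Delta t$ exceeds half a grid unit, which
  never occurs at contractile activities of this magnitude).
* **Degenerate inputs.** Isotropic sites ($S \approx 0$) carry an
  `isotropic` flag; their director angle is 0 by convention and they are
  excluded from misalignment statistics. An isotropic stress tensor has an
  undefined principal axis and is flagged the same way.

## Simulation protocol and problem sizes

The full protocol is a $200 \times 200$ periodic box run for 120,000 steps
with frames every 300 steps, random initial directors at $S = 1$;
measurements are taken in the statistical steady state, detected as the
earliest frame from which neither the defect count nor the extensile area
fraction shows a Mann–Kendall trend (two-sided, $\alpha = 0.05$, minimum
window 50 frames), averaging the final 150 frames.

The test-suite and acceptance-script runs use the reduced protocol —
$128 \times 128$, 39,900 steps, final 50 frames — which reproduces the
full-box statistics (the extensile fraction is intensive; we verified
$96^2$, $128^2$ and $200^2$ agree within a percentage point) at desk-scale
runtime. The pinned-defect scenario runs at the full $R = 80$ island
geometry in the acceptance suite, and at reduced geometry ($R = 26$–$40$)
in unit tests of the mechanism.

## Measurement stack

The same operations serve simulation frames and experiment-like data:

1. **Director construction.** Per-cell tables are mapped to a square
   lattice with spacing $dl = L/\sqrt{N}$ (closest site; nearest cell wins
   collisions, ties broken by input order; empty sites filled from the
   nearest occupied site). Interpolation — for refining coarse lattices
   before defect detection — always operates on $(\cos 2\psi, \sin 2\psi)$:
   linear interpolation of raw angles is ill-defined at the 180° wrap (the
   nematic midpoint of 10° and 170° is 0°, not 90°).
2. **Principal stress axis.** The measured stress tensor is made traceless
   ($c = -(\sigma_{xx}+\sigma_{yy})/2$ added to the diagonal); $\mathbf{m}$
   is the eigendirection of the positive (outward-pulling) principal
   stress, $\theta_p = \tfrac12\mathrm{atan2}(2\sigma_{xy},
   \sigma_{xx}-\sigma_{yy})$.
3. **Defects.** Plaquette winding numbers with corner differences wrapped
   to $(-\pi/2, \pi/2]$; windings of $\pm\pi$ are $\pm 1/2$ defects;
   adjacent same-charge plaquettes merge at their centroid. Orientations
   come from the Q-gradient polarity ($+1/2$: the comet axis
   $\mathrm{atan2}(\langle\partial_x Q_{xy} - \partial_y Q_{xx}\rangle,
   \langle\partial_x Q_{xx} + \partial_y Q_{xy}\rangle)$; $-1/2$: one of
   the three symmetry axes, reported mod $2\pi/3$) — any
   rotation-equivariant convention is acceptable and this one is fixed
   here. On a periodic domain the total charge is identically zero.
4. **Interface domains.** A site is interface if its Euclidean distance to
   the nearest opposite-class site is at most the stress resolution
   (5.2 µm ≈ 1.73 lattice units), computed with a distance transform on a
   wrap-padded array. Interface sites are removed from the
   extensile/contractile tallies so the three fractions partition the
   tissue.
5. **Correlation functions.** The nematic correlator $C(r) = \langle\cos
   2(\psi(r_0+r) - \psi(r_0))\rangle$ (and its temporal analogue) via
   mask-normalized FFT autocorrelation, radially binned; island statistics
   restrict to a central disc to avoid edge effects. Decay lengths are
   read off at the $1/e$ crossing with linear interpolation.

## The synthetic generator

`generate_frames()` emulates the structure the pipeline assumes in measured
monolayer data: a 1 mm circular island, ~2,500 cells per frame, frames
every 15 min; shape orientations from Gaussian-filtered white noise on the
nematic components with the filter width calibrated so the measured $1/e$
correlation length equals the configured 100 µm (the calibration inverts
the exact angular correlation of two correlated Gaussian unit vectors,
$E[\cos\Delta\phi] = \tfrac{\pi}{4}\rho\,{}_2F_1(\tfrac12,\tfrac12;2;\rho^2)$,
verified by Monte Carlo); AR(1) temporal mixing tuned the same way to a
300-min persistence; stress orientations built as the angle of
$\beta\,(\cos 2\psi_n, \sin 2\psi_n) + \mathbf{g}$ with $\mathbf{g}$ a unit
noise vector carrying the 50 µm stress correlation length. For that
mixture the site-wise extensile probability is exactly
$\arccos(\beta)/\pi$, so $\beta = \cos(\pi p)$ hits any target fraction
$p$ without iteration. Stress magnitudes decline with $\theta$
(fixture law $0.35 + 0.65\cos^2\theta$ times log-normal noise — the true
joint law is only known as a binned curve) and tensors are reassembled from
(orientation, magnitude, isotropic part) on a 5.2 µm grid. Cells read the
fields at their nearest lattice site (≤ 2.6 µm offset), which keeps the
per-cell misalignment distribution exactly as calibrated.

What the generator does *not* emulate: mechanical force balance within the
stress field, cell shapes and neighbour topology, segmentation noise, and
island-edge anisotropy. Passing round-trip tests therefore demonstrate that
the *pipeline* recovers configured statistics, not that the generator is a
model of real tissue.

Because extensile/contractile clusters have the stress correlation length,
one island holds only a few hundred independent patches; recovery tests
pool several islands, exactly as the experimental statistics pool replicate
monolayers.

## Sensitivity, and what the defaults reproduce

At the default (printed) parameter set the model produces the qualitative
phenomenology robustly: activity sustains a defect-laden turbulent steady
state with extensile clusters in a contractile background; switching
activity off ($\zeta = 0$) relaxes the tissue to a defect-free aligned
state with zero extensile area; defects sit overwhelmingly on
extensile/contractile interfaces (≈ 86% colocalization in the reduced run);
and shape orientations are correlated over longer distances than stress
orientations.

Quantitatively, the steady-state extensile area fraction at the defaults is
≈ 2–3%, an order of magnitude below the ≈ 28% reported for this model
class, and the pinned-defect scenario relaxes to full alignment rather than
a metastable extensile patch. Our sensitivity study (reproducible with
`simulate_monolayer()` over parameter variations) shows both statistics are
controlled almost entirely by the alignment coupling: the quartic coupling
at $J \approx 1.1\times10^{-4}$ — about 7× weaker than the default, i.e. a
misalignment relaxation time of roughly an hour — yields ≈ 28% extensile
area and tens-of-lattice-unit metastable patches, while no tested variation
of the other ingredients (back-stress, coupling form at fixed $J$,
viscosity, bulk scale, stiffness ratio, box size, run length) moves the
fraction by more than a factor of ~3. We deliberately keep the printed
constants as defaults rather than recalibrating them against reported
outputs; users studying the high-misalignment regime should lower `J` (or
use the harmonic coupling with a correspondingly small `J`) explicitly.

## Known limitations

* Explicit Euler for the tensor fields limits time resolution to the LB
  step; no sub-stepping is provided.
* The passive stress omits elastic back-reaction by default (see above).
* Defect orientations use a fixed local-gradient convention; comparing
  against other codes may require a constant rotation.
* The steady-state detector assumes roughly stationary noise; strongly
  intermittent series can defeat the Mann–Kendall window and fall back
  (flagged) to the trailing measurement window.

## A worked example

```{r example, eval = FALSE}
library(activenematic)

cfg  <- run_config(grid = 128, steps = 39900, frame_every = 300, seed = 1,
                   store_flow = FALSE)
traj <- simulate_monolayer(cfg, model_params("mdck"))
summ <- summarize_run(traj, measure = 50)
round(summ$means, 2)
#>      ext_pct interface_pct     coloc_pct  defect_count
#>         2.17          6.21         86.86         23.16
```

The same `summarize_run()` output feeds `write_report()`, and the
`inst/cli/activenematic` script chains simulate → analyze → report from a
shell.
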