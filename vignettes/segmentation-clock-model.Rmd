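---
title: "A physical model of the zebrafish segmentation clock: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A physical model of the zebrafish segmentation clock: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

psmclock simulates the zebrafish segmentation clock as a population of noisy
phase oscillators carried by motile, mechanically interacting cells inside a
deforming tissue. The presomitic mesoderm (PSM) is represented as two tubes of
radius $r_0$ whose axes run along the anterior–posterior (x) axis; the tailbud
joins them posteriorly as a half torus of core radius $R$. All positions are
measured in the tailbud frame: the posterior tip is fixed at $x = L_x$ and the
anterior end of the PSM sits at $x_a(t)$, so the PSM length is
$L(t) = L_x - x_a(t)$.

### Cell mechanics

Each cell is a particle with position $\mathbf{x}_i$, oscillator phase
$\theta_i$ and polarity unit vector $\mathbf{n}_i$, obeying the overdamped
equation of motion

$$\dot{\mathbf{x}}_i = \mathbf{v}_d(x_i) + v_0(x_i)\,\mathbf{n}_i
  + \sum_{j \ne i} \mathbf{F}(\mathbf{x}_i, \mathbf{x}_j)
  + \mathbf{F}_b(\mathbf{x}_i).$$

* **Advection** $\mathbf{v}_d = (-v(\chi), 0, 0)$, $\chi = (x - x_a)/L$,
  describes axis elongation viewed from the tailbud. $v(\chi)$ is piecewise
  linear with $v(0) = v_a$, $v(1) = 0$ and a slope change at $\chi = x_q$
  controlled by the posterior parameter $v_p$; its gradient is the local
  strain rate, so $v_p < v_a$ concentrates deformation anteriorly and
  $v_p = v_a$ gives a uniform strain rate. $v_p$ switches from `vp_early` to
  `vp_late` at time `tg` to represent the developmental change in advection
  pattern.
* **Intrinsic motility** $v_0(\chi) = v_s [1 + ((1-\chi)/X_v)^h]^{-1}$ is a
  posterior-high mobility gradient (random cell mixing is strongest in the
  tailbud). The polarity performs an isotropic random walk on the unit
  sphere: the update takes a Gaussian step of size $\sqrt{2 D_\varphi\,dt}$
  in the local tangent plane and renormalizes. We integrate the walk in this
  tangent-plane form rather than as Langevin equations for the two spherical
  angles: the two are equivalent to $O(dt)$, but the angle form has
  coordinate singularities at the poles whereas the tangent-plane step is
  regular everywhere; its stationary law is uniform on the sphere, which the
  test suite verifies by a Kolmogorov–Smirnov test on $\cos\phi$.
* **Repulsion** is a linear elastic contact force of magnitude
  $\mu(1 - d/d_c)$ for inter-cell distance $d$ below the cell diameter
  $d_c$, zero beyond. Coincident cells are separated along a direction
  derived deterministically from the pair ids, so runs stay reproducible.
* **Confinement** acts along the inward wall normal with magnitude
  $\mu_b e^{-(r - \rho)/r_b}$, where $\rho$ is the local radial coordinate
  in the tube or torus. We deliberately use this wall-normal form: writing
  the decay per Cartesian component with component-wise wall distances makes
  the force asymmetric between the $+y$ and $-y$ walls and essentially
  removes confinement at oblique angles, which breaks the invariants the
  force must satisfy (magnitude $\mu_b$ anywhere on the wall, continuity
  across the tube–torus junction, no escape beyond a few $r_b$). The
  radial form preserves the printed wall magnitude and decay length.

### Phase dynamics

$$\dot{\theta}_i = \omega(x_i)
 + \frac{\kappa(t)}{n_i}\sum_{|x_j - x_i| \le d_c} \sin(\theta_j - \theta_i)
 + \sqrt{2 D_\theta}\,\xi_i(t),$$

with $n_i$ the number of neighbours (no coupling term when $n_i = 0$). The
frequency profile $\omega = \omega_0 [\sigma + (1-\sigma)
(1 - e^{-k\chi})/(1 - e^{-k})]$ is highest at the posterior tip and generates
kinematic waves that travel posterior→anterior; $\sigma$ is the
anterior/posterior frequency ratio. Delta-Notch inhibition (DAPT) is modelled
by the coupling schedule $\kappa(t) = 0$ before the washout time and
$\kappa_s t + \kappa_0$ after it; $\kappa_s > 0$ represents a developmental
increase in coupling strength.

Cells crossing the anterior end ($x < x_a$) arrest: their phase freezes and
they advect anteriorly at the boundary speed $v_a$, inert to forces and
coupling. The frozen phase field forms stripes whose wavelength is the
segment length $S = v_a T_a$ ($T_a$ = anterior period); stripes are the
model's segment boundaries.

### Tissue programs

PSM shortening moves the anterior end at speed $u_a$ ($x_a = u_a t$); the
constraint $v_a + u_a = c$ keeps the segment length fixed across shortening
speeds. Because waves then run into an approaching boundary, the anterior
period is Doppler-shifted; `tune_anterior_period()` recalibrates $\omega_0$
by proportional iteration on noise-free probe runs (discarding the
wave-formation transient, about one transit time $L/v_a$) until the measured
anterior period is back at $T_a$ (tolerance 1%). The tube radius may shrink linearly,
$r(t) = r_0 - s_r t$; cells left outside after a radius update are placed
back at $\rho = r - 2 r_b$.

Cell number is regulated by local density: when a cell leaves through the
anterior end, the per-region densities (left tube, right tube, tailbud,
using analytic region volumes) are compared with the target $\varrho_0$ and
one cell is inserted into the most depleted region — uniformly at random in
that region, never within $\zeta$ of the anterior end of the tubes — with a
uniformly random phase and polarity. Ties are broken left → right → tailbud.
Random-phase insertion is one of the model's two noise sources (the other is
$D_\theta$); it is what ultimately degrades the pattern in desynchronization
conditions.

### Integration and reproducibility

All equations are integrated with the Euler–Maruyama method at
$dt = 0.01$ min. Neighbour search inside the stepper uses a Verlet list:
all pairs within $d_c + 3$ µm are cached and re-checked against the exact
cutoff $d_c$ every step, and the list is rebuilt (via a uniform spatial
grid) whenever any cell has moved more than half the 3-µm skin since the
build, so cutoff semantics remain exact while the dominant cost drops by
about half. The single-call force assembly (`net_velocities()`) uses the
per-call grid and is checked against an all-pairs oracle to $10^{-12}$. Randomness comes
from four xoshiro256++ streams derived from the run seed (initialization,
phase noise, polarity noise, insertion), so a run is bit-reproducible given
its configuration and seed, and disabling one noise channel does not shift
the draws of another. Initialization places $N = \varrho_0 \times$ volume
cells uniformly, relaxes the packing for 10 min with advection off and an
extra wall at $x = x_a$, then assigns phases (all at $3\pi/2$ for the
synchronized condition, i.i.d. uniform for resynchronization).

Within a step the update order is: pair sums → positions and phases →
polarity → arrested-cell advection → schedules ($x_a$, $r$, $\kappa$) →
arrest and density-controlled insertion → pruning of long-arrested cells.
Order effects are $O(dt)$. Arrested cells are dropped after a configurable
retention window (default 150 min) since they are inert; runs that score
the whole arrested pattern extend the window to the run duration.

## Default parameters

| parameter | default | units | meaning |
|---|---|---|---|
| $r_0$, $R$, $L(0)$ | 25, 50, 325 | µm | tube radius, torus core radius, PSM length |
| $\mu$, $d_c$ | 8.71, 11 | µm/min, µm | repulsion strength, cell diameter |
| $\mu_b$, $r_b$ | 20, 1 | µm/min, µm | boundary force, decay length |
| $v_s$, $X_v$, $h$, $D_\varphi$ | 1.0, 0.4, 3, 0.1 | µm/min, –, –, 1/min | motility gradient and polarity noise |
| $v_a$, $x_q$ | 55/30, 0.5 | µm/min, – | anterior advection speed, profile knot |
| $\omega_0$ | $2\pi/30 \approx 0.2094$ | rad/min | posterior frequency |
| $\sigma$, $k$ | 0.7, 3 | – | frequency-profile ratio and shape |
| $\kappa_0$, $D_\theta$ | 0.07, 0.0013 | 1/min | coupling strength, phase noise |
| $\vartheta$, $T_a$ | $3\pi/2$, 30 | rad, min | stripe phase, anterior period |
| $\varrho_0$, $\zeta$ | 0.0015, 100 | µm$^{-3}$, µm | target density, no-insertion margin |

$v_a = 55/30$ µm/min makes the segment length $v_a T_a = 55$ µm $= 5 d_c$.
$\varrho_0$ corresponds to 998 cells in a $110 \times 110 \times 55$ µm³
box. Where a quantity is not pinned by a printed anchor ($v_s$, $X_v$, $h$,
$D_\varphi$, $\sigma$, $k$), the default is chosen to give a posterior-high
mobility gradient and wave pattern of realistic shape, and is overridable in
every configuration block.

## Observables

**Local phase order.** $Z_m e^{i\Psi_m}$ is the mean unit phasor over the
cells of one side in a thin axial slice of width $\Delta x = d_c$; the local
order $Z(t,x)$ averages the moduli of $M = 5$ consecutive slices.
Slice-first averaging keeps $Z$ high across a smooth phase gradient, which a
single thick slab would wash out. Sector and slice phase averages are always
phasor (circular) means — arithmetic averages of angles are ill-defined
across the $0/2\pi$ cut.

**Segment records.** Boundary-setting times $\tau_i$ are upward crossings of
the unwrapped first-slice mean phase $\Psi_1(t, x_a)$ through $\vartheta$,
linearly interpolated between samples, with crossings closer than $T_a/2$
merged. A boundary is *normal* when $Z(t, x_a) \ge Z_c = 0.85$ at every
sample in the window $[\tau_i - T_a/2,\ \tau_i - T_a/2 + \eta]$,
$\eta = 4$ min. Normal boundaries are numbered by chaining (previous normal
boundary $j$ → this one is $j+1$) or, after a gap, from the event time with
tolerance $\Delta = 0.3$; all remaining indices are defective. From the
labelled record we derive the anterior limit of defects (ALD, first
defective index), the first recovered segment (FRS $= j_f - 1$ with $j_f$
the first normal index; the experimental convention — first normal after
segment 9 — is available by flag) and the posterior limit of defects (PLD,
last defective index). Runs must be long enough that the classification
window of the last scored boundary is covered; the record length defaults to
$\lfloor \text{duration}/T_a \rfloor - 1$, and a record whose defects reach
that end is right-censored (its PLD is a lower bound).

**Desynchronization stripe scoring.** The $Z_c$ window rule above is the
scorer for *recovery* conditions. Desynchronization outcomes are scored on
the formed pattern instead, mirroring how embryos are scored by eye:
`stripe_coherence_record()` locates stripes in the arrested phase field and
attaches to each the circular resultant of locally detrended phases
($\theta_i - 2\pi(x_i - x_c)/S$ within half a segment of the stripe). A
stripe is *recognizable* while this coherence is at least 0.5 — the midpoint
between a perfect stripe (1) and a fully randomized field (≈0), fixed a
priori — and the pattern's ALD is one past the leading run of recognizable
stripes. Under the strict $Z_c$ rule a desynchronizing tissue already fails
at the second boundary, because density-regulating insertion makes the
anterior cell population partly random-phased well before the stripes
visually dissolve; the coherence scorer reflects the pattern-based
definition that the embryonic ALD uses.

**Phase vorticity.** Following the off-lattice vortex index, cells of one
side are projected onto four 20-µm slices (two z-slices for z-axis vortices,
two y-slices for y-axis ones). On a grid ($\Delta x = 5$ µm transverse
$\Delta = 2$ µm), a ring of inner radius $\delta_l = 5.5$ µm and width
$l = 14$ µm is divided into six sectors; sector phasor means are cyclically
permuted to start at the minimum (ascending index for one handedness,
descending for the other) and regressed against sector index $i = 0..5$
(index mean $5/2$, variance $35/12$). A grid point carries vorticity
$\psi = (\hat\theta_5 - \hat\theta_0)/2\pi$ when the correlation exceeds
$\alpha$ *and* $\psi \ge \psi_{\min}$; any empty sector vetoes the point.
Profiles take the maximum over the transverse grid, then over the four
planes, per handedness. The thresholds $\alpha$ and $\psi_{\min}$ are
calibration constants: we set $\psi_{\min} = 0.6$ and calibrated
$\alpha = 0.97$ on noiseless planted vortices so that detections cluster
within about two grid cells of the core while uniform fields and pure axial
phase gradients — the critical false-positive control, since a gradient
ring is *not* cyclically monotone — produce none.

**Left–right statistics.** Over boundary loci posterior to segment 9, $N_t$
counts loci defective on at least one side, $N_s$ those defective on exactly
one, and $F_s = N_s/N_t$. Under left–right independence with per-side defect
probability $p$, $F_s = 2(1-p)/(2-p)$; the fixtures module generates
Bernoulli records to exercise this null.

## The synthetic fixtures

`make_planted_field()` draws uniform cell positions in a box and assigns
phases by rule — uniform, axial gradient, i.i.d. random, or an ideal
winding-±1 vortex about the y or z axis. These fields are the oracles for
the order and vorticity machinery: the planted vortex must be detected at
its core and the gradient must not fire the detector. They emulate the
geometry-free content of a tissue snapshot; they do not emulate confinement,
the frequency profile, or the spatial correlations of a real simulation, so
passing detector tests on them establishes the detector's correctness, not
the biology of vortex formation (which the engine runs probe separately).
`make_toy_record()` generates the Bernoulli left/right records for the
independence statistics.

## Problem sizes used by the test suite

The study conditions above (full geometry, 100 realizations in the original
analyses) are too heavy for a routine test run, so the suite fixes reduced
designs, chosen once:

* **Deterministic anchors** (posterior period; arrested stripe wavelength)
  run at the full geometry, noise off or at default, single runs of 180 and
  300 min.
* **Desynchronization (ALD / stripe counting)** runs keep the model's axial
  insertion geometry exactly (tube length 250 µm, $\zeta = 100$ µm) but use
  a moderately thinner tube ($r_0 = 16$ µm, $R = 30$ µm): the
  stripe-coherence ALD is governed by the accumulated random-cell fraction
  and phase diffusion, which depend on the axial geometry, not on the tube
  radius (radius only sets the per-stripe statistics). Ten seeded
  realizations per noise condition, 240 min each, scored per side.
* **Qualitative parameter effects** (PSM length, posterior advection,
  tailbud mixing, coupling strength) use a reduced geometry
  ($r_0 = 13$ µm, $R = 30$ µm, $L = 200$ µm baseline vs 280 µm for the
  long-PSM condition) with ten seeded realizations per condition and
  durations (480–600 min) long enough that the baseline PLD is not
  right-censored. The no-insertion margin keeps its full value
  $\zeta = 100$ µm in every condition: it is a synchronization *time*
  margin ($\zeta/v_a \approx 55$ min for inserted cells to entrain before
  reaching the anterior), and shrinking it with the tissue floods the
  anterior with unentrained cells and destroys recovery altogether.
  A caveat is unavoidable here: at this scale the tube diameter
  is only ~3 cell diameters and persistent phase vortices — the structures
  whose transport delays the posterior limit of defects at full scale — do
  not survive transit. Local effects (coupling strength; the invariance of
  FRS to tissue-level parameters) express clearly in the reduced tissue,
  but the transport-mediated effects of PSM length and posterior advection
  speed invert or vanish: a disordered domain that spends longer in transit
  heals before it reaches the anterior. The corresponding checks in the
  test suite assert the full-scale directions and therefore document this
  limitation by failing at desk scale rather than silently weakening the
  assertion.

What the reduced designs can show is the local-mechanism behaviour at desk
scale; they do not reproduce the quantitative FRS/PLD medians of the
full-scale, 100-realization sweeps, which additionally depend on parameter
values not printed in the main text.

## Known limitations

* Coupling delays in Delta-Notch signalling are omitted (as in the source
  model, to keep integration cheap); segment length is constant over
  development; there is no explicit gene-regulatory network.
* The phase-noise intensity is uniform across the tissue.
* Scoring uses the mean phase and order of thin anterior slices;
  morphological boundary formation is not modelled.
* The Euler–Maruyama integrator is first order; halving $dt$ halves phase
  errors (verified on frozen positions), but particle trajectories are
  chaotic, so individual positions decorrelate between $dt$ choices while
  statistical observables are stable.
* At the reduced test scales, tube diameters of ~3 cell diameters suppress
  the persistent vortices that dominate recovery at full scale.
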