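---
title: "Microstructural and discrete monodomain models of fibrotic cardiac tissue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microstructural and discrete monodomain models of fibrotic cardiac tissue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardiomaze)
```

## The scientific problem

Microfibrosis — the fine-grained interleaving of excitable myocytes and
nonconducting material at single-cell scale — can turn a patch of cardiac
tissue into an *ectopic pacemaker*: the fractionated, zig-zag propagation
through the surviving strands of a fibrotic "maze" can re-excite tissue
behind the wave and sustain reentry. `cardiomaze` provides the two coupled
simulators needed to study this quantitatively, and the analysis pipeline
that relates the fraction of nonconducting cells $\phi$ to reentry
probability and to the directional percolation thresholds of the cell
network.

## The microscopic model

Tissue is resolved on a uniform grid of $8\,\mu m \times 8\,\mu m$ volumes
of depth $d = 10\,\mu m$, each assigned to one myocyte. The transmembrane
voltage obeys the heterogeneous monodomain equation

$$\beta C_m \frac{\partial V}{\partial t} + \beta I_{ion}(V, \eta)
  = \nabla \cdot (\sigma \nabla V) + I_{stim}, \qquad
  \frac{\partial \eta}{\partial t} = f(V, \eta),$$

with no-flux boundaries. Heterogeneity enters exclusively through the face
coefficients of the finite-volume discretization: each interior face of the
grid carries one of five connection types — membrane ($\sigma_m = 0$),
cytoplasm ($\sigma_c = 0.4\,\mu S/\mu m$), or one of three gap-junction
classes whose lumped conductances are spread over the depth, $G/d$: plicate
($G_p = 0.5\,\mu S$, aligned end-to-end abutments), interplicate
($G_i = 0.33\,\mu S$, stepped/offset longitudinal contacts) and combined
plicate ($G_c = 0.062\,\mu S$, lateral side-to-side contacts).

Time stepping uses Godunov operator splitting. The reaction stage advances
the stiff ionic ODEs with explicit Euler at $\Delta t_o = 10^{-4}$ ms
(chosen for stability of the Markov-chain kinetics; a Rush–Larsen variant
offers no step-size advantage for Markov-chain models and is not used). The
diffusion stage is the unconditionally stable implicit Euler scheme

$$\alpha V^{n+1}_{i,j} - \sum_{faces} \sigma_{face} (V^{n+1}_{nb} -
  V^{n+1}_{i,j}) = \alpha V^{*}_{i,j}, \qquad
  \alpha = \frac{\beta C_m h^2}{\Delta t_p},$$

assembled once as a sparse symmetric positive-definite matrix whose
Cholesky factorization is cached; every row sums to $\alpha$, which makes
uniform fields exact fixed points and yields discrete conservation of
$\sum V$ (microscopic) and $\sum_i A_i V_i$ (discrete model). The default
$\Delta t_p = 0.01$ ms ($N_o = 100$ substeps); a refinement test in the
suite guards the accuracy of this choice. The stimulus current is applied
in the reaction (ODE) stage.

## The frozen template microstructure

The basic unit is a deterministic, versioned layout of 32 myocytes on a
$60 \times 18$ volume grid ($480 \times 144\,\mu m$): two side-by-side
half-units whose row banding is vertically offset so that every
longitudinal contact between half-units (and across tile seams) is stepped,
with per-row cell splits whose breakpoints are staggered row-to-row, and
two interdigitated splits. Widths are 2 or 3 volumes (16/24 $\mu m$),
lengths 10–21 volumes. The realized statistics are

```{r stats}
cell_geometry_stats(build_template())
```

against targets of $120.9 \pm 27.8\,\mu m$ length, $18.3 \pm 3.5\,\mu m$
width and 6 neighboring myocytes per cell. Exact cell-by-cell geometry is
not a contract — only these statistics and the connectivity class are. The
unit tiles periodically: wrap-around face types are stored with the unit
and reused at seams, so every cell of a tiled tissue is a translate of a
template cell.

### Gap-junction placement and conduction-velocity calibration

The conductances above are fixed; what the literature does not pin down is
*which* faces of each intercellular contact carry junctions. Placement is
therefore parameterized by coverage fractions per contact class plus a
`lateral_interplicate` fraction: the faces at the two ends of each
side-to-side contact belong to the intercalated-disc region and carry
interplicate junctions. At least one junction face per contact is always
kept, so cell adjacency — and with it all percolation results — is
independent of the coverage calibration.

The frozen defaults (plicate 1.0, interplicate 0.6, combined plicate 0.7,
lateral interplicate 0.55, with $\beta = 0.14\,\mu m^{-1}$ and $C_m =
1\,\mu F/cm^2$) were calibrated once so that homogeneous conduction
velocities with the Bondarenko kinetics reach $410\,\mu m/ms$ along the
fibers (LP) and $130\,\mu m/ms$ transversally (TP), ratio 0.32. Measured on
strips of $\geq 0.3$ cm with interior probes: LP $\approx 411$–$418$, TP
$\approx 128$. $\beta$ and $C_m$ give a whole-cell capacitance of
$\approx 30$ pF for the mean myocyte, in the murine range. Purely lateral
combined-plicate coupling cannot reach $130\,\mu m/ms$ at any coverage
(it saturates near $90\,\mu m/ms$), which is why the intercalated-disc
promotion parameter exists.

## The ionic models

`bondarenko_model()` is a port of the Bondarenko et al. (2004) mouse left
ventricular (apex) model: 15 transmembrane currents, Markov chains for the
fast Na$^+$ channel (9 states), the L-type Ca$^{2+}$ channel (8), the rapid
delayed rectifier (5) and the ryanodine receptor (4), Hodgkin–Huxley gates
for the other K$^+$ currents, and full intracellular Ca$^{2+}$ handling.
All 44 chain/gate/concentration states are integrated explicitly (41
independent), so chain occupancies are conserved by construction; the suite
asserts drift $< 10^{-4}$ over $10^5$ steps. Voltage-dependent rates are
tabulated on a 0.05 mV grid and linearly interpolated — a standard
optimization that changes single-cell traces by far less than the Euler
discretization error.

Two port-calibration choices departed from the values we could not
reconstruct exactly from the publication: the open-state inactivation rate
of the Na$^+$ chain uses the $9.178\,e^{V/29.68}$ form (without it the
window current locks the cell at a $-25$ mV quasi-plateau), and the inward
rectifier conductance is set to $0.55\,mS/\mu F$, the upper murine range,
giving $APD_{90} = 19.5$ ms — typical mouse epicardium. The frozen initial
state is the model's own quiescent steady state after 5 s of stimulus-free
integration (residual $|dV/dt| < 10^{-7}$ mV/ms); fidelity of the waveform
to the original publication is qualitative (rapid upstroke, overshoot,
$APD_{90}$ well under 100 ms), not a quantitative target.

`surrogate_model()` is a two-variable excitable model (Mitchell–Schaeffer
form mapped to the physiological voltage range, $V = -82 + 120u$ mV) for
solver tests and Monte-Carlo ensembles. Its four time constants are fixed
once to put it on the murine tissue scales of the Bondarenko model:
$\tau_{in} = 0.32$ (upstroke; LP conduction velocity $\approx 407\,\mu
m/ms$), $\tau_{out} = 6$, $\tau_{close} = 9$ (tissue APD $\approx 29$ ms),
$\tau_{open} = 30$ (tissue effective refractory period 50–60 ms by S1–S2
measurement, vs. murine 40–60 ms). Earlier working values
($\tau_{close} = 24$, $\tau_{open} = 90$) produced APD 55 ms and ERP above
100 ms — not a murine cell — and were replaced when the S1–S2 measurements
were first made; this is the only recalibration the surrogate received.

### Stimulus amplitudes

The study protocols stimulate a plane (left or bottom edge) for 2 ms
at twice diastolic threshold. A threshold measured on an isolated cell is
meaningless in tissue — the electrotonic load of coupled quiescent
neighbors raises the plane threshold by an order of magnitude (measured:
12.7 vs. 96 pA/pF for Bondarenko) — so the frozen defaults are twice the
*tissue* plane threshold, bisected once with the actual edge-band protocol,
using the transversal direction (the higher of the two): 368 pA/pF
(Bondarenko, whole-cell discrete), 800 (Bondarenko, 2-volume microscopic
band), 193/280 (surrogate). The microscopic band values are larger because
the band drives far less membrane per stimulated element.

## The discrete model

Each myocyte becomes one isopotential node with volume $A_i d$
($A_i$ = volume count $\times h^2$) obeying

$$A_i d\, \beta C_m \frac{dV_i}{dt} + A_i d\, \beta I_{ion}
  = \sum_{j \in nn_i} G_{i,j}(V_j - V_i) + I^{stim}_i,$$

time-stepped with the same splitting. The equivalent conductances come
from series/parallel reduction of the microstructure: each gap-junction
face $k$ between cells $i,j$ contributes a series resistance

$$R_{i,j,k} = \mathrm{dist}_{i,j,k}\,\frac{1}{\sigma_c h} + \frac{1}{G_k},$$

where $\mathrm{dist}$ is the Manhattan distance from the reference volume
of each cell to its junction volume (applied literally as index
arithmetic, with no path search around obstacles), and the junctions of a
pair combine in parallel, $G_{i,j} = \left(\sum_k R_{i,j,k}^{-1}\right)$.
The reference volume $pr_i$ is the cell volume nearest the cell centroid,
ties broken toward the lowest $(x, y)$ index — a deterministic choice
matching the intuition of a lumped isopotential node. Volume indices are
1-based (R convention) throughout.

The Manhattan-path series resistance is itself an approximation of the
two-dimensional intracellular medium: on the two-cell oracle meshes it
agrees with exact nodal analysis of the volume-level resistor network to
within $\sim$25% (tested as a reported bound, not asserted tighter), while
the hand-evaluated reduction formulas are exact to $10^{-12}$. What makes
the discrete model quantitatively equivalent to the microscopic one is the
conduction-velocity calibration plus this reduction: on homogeneous strips
the two models' conduction velocities agree within 5% and single-probe AP
traces superimpose within 5 mV after aligning activation times.

## Fibrosis, reentry and percolation

A fibrosis realization at fraction $\phi$ removes all gap junctions of
`round(phi * N)` cells (rounding half away from zero) drawn uniformly
without replacement with a seeded generator; mesh-level and network-level
removal commute with the reduction, and a realization is reproducible from
`(phi, seed)` alone. $\phi = 0$ is the homogeneous tissue; $\phi = 1$ is
inert.

Reentry is operationally defined as remaining activity (any $V > V_{act}$,
default $-60$ mV) at $t_{traverse} + 60$ ms, where $t_{traverse}$ is the
time a fractionated wave near $\phi = 0.45$ needs to cross the tissue:
$\approx 60$ ms/cm longitudinally, $\approx 240$ ms/cm transversally. For
the 1 cm study tissue this reproduces the canonical check times of 120 ms
(LP) and 300 ms (TP); `reentry_check_time()` scales them for other
extents. Per-cell activity is classified NA / A / S / NS (none; single AP;
sustained reentry, $\geq 2$ APs with activity at the end; nonsustained,
$\geq 2$ APs with early extinction plus a stop time), counting APs as
upward crossings of $-30$ mV with a $-60$ mV re-arming hysteresis to avoid
double-counting notched upstrokes.

Side-to-side connectivity of a realization is evaluated on the cell
network by union-find over retained links (left–right for LP, bottom–top
for TP), so mesh and network analyses agree by construction. The
percolation curve $C(\phi)$ is the fraction of seeded realizations with a
spanning path; the threshold $\phi_c$ comes from a straight-line fit
through the transition points $C \in [0.1, 0.9]$ solved at $C = 0.5$ (a
logistic fit is available behind a flag). On the full 1 cm $\times$ 1 cm
network (47,040 cells) with 100 seeds per $\phi \in [0.40, 0.60]$ this
yields $\phi_c \approx 0.525$ (LP) and $\approx 0.464$ (TP) — the
anisotropic splitting of the $\approx 0.5$ threshold expected for a
6-neighbor network, induced by the elongated cell geometry (the 1 cm
square is $\sim$84 cells long but $\sim$560 cells tall in graph distance).

## Ensembles and problem sizes

`run_ensemble()` drives seeded Monte-Carlo ensembles (per-realization seed
= base seed + 1000 $\times$ phi-index + realization index; summaries carry
Wilson 95% intervals) with quiescence early-stopping: a run whose maximum
voltage stays below $-70$ mV for 10 ms after the stimulus cannot re-excite
and is terminated, which also yields the NS stop times.

The test suite exercises the full-fidelity physics at sizes a single CPU
handles in minutes — conduction velocities on $\geq 0.3$ cm strips
($\sim$300–800 cells discrete, 4,320 volumes microscopic), percolation on
the full 1 cm network, and a reentry ensemble with the surrogate kinetics
on a 0.4 cm $\times$ 0.4 cm tissue (8,064 cells, 20 seeds per $\phi \in
\{0.30, 0.45, 0.60\}$, $\Delta t_p = 0.05$ ms). In that scaled ensemble
the probability of reentry is zero at $\phi = 0.30$ (the wave traverses
and dies) and at $\phi = 0.60$ (above the percolation threshold nothing
propagates), and positive near the threshold — the qualitative signature
of the full-scale experiment, whose published shape (peak near
$\phi = 0.48$, 100 seeds, 16 $\phi$ values, 41-state kinetics, 1 cm$^2$)
requires a cluster-scale budget; the same `ensemble_spec()` with
`ionic = "bondarenko"`, the full grid and `n_realizations = 100` is that
experiment. The surrogate is used for ensemble-scale screening because a
single 0.4 cm Bondarenko run at $\Delta t_o = 10^{-4}$ ms costs over an
hour of CPU; all printed conduction-velocity anchors use the Bondarenko
kinetics.

What the scaled ensemble does *not* show: the quantitative location and
height of the $P(\phi)$ peak (domain size shifts the observable peak
toward the percolation threshold — reentrant circuits need room), the
NS-vs-S balance over long horizons, and any effect of the true Markov-chain
restitution kinetics on maze reentry.

## Numerical choices and degenerate inputs

* Linear solves: cached sparse Cholesky (`Matrix`); a residual check
  ($10^{-6}$ relative) guards each step. Uniform fields and
  membrane-decoupled volumes are exact fixed points.
* NaN guard after every reaction stage, naming the first offending state
  variable and cell.
* Surrogate state is clamped to $u \in [-0.05, 1.05]$, $h \in [0, 1]$
  against stimulus overshoot.
* Meshes that are not tileable cannot be tiled (error); simulations
  require `T_end` to be a multiple of $\Delta t_p$ and ensembles round the
  check time up to the next step.
* Empty stimulus regions, non-adjacent cell pairs in the reduction, and
  percolation curves that do not span $C = 0.5$ raise errors rather than
  returning extrapolations.

## Known limitations

* Two-dimensional tissue only; no surrounding healthy tissue around the
  fibrotic region, no bidomain/extracellular potentials, no
  myocyte–fibroblast coupling, no electrogram computation.
* The Bondarenko port is a good-faith reconstruction: two rate/conductance
  choices documented above are calibrated rather than transcribed, and
  waveform fidelity is qualitative.
* The reduction's Manhattan-path resistance is systematically biased
  relative to nodal analysis of the 2-D cytoplasm (by design, following
  the series-resistor formulation); the conduction-velocity calibration
  absorbs this bias at tissue level.
* Percolation thresholds are finite-size quantities; they are computed on
  the same 1 cm network as the study, not extrapolated to the infinite
  lattice.
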