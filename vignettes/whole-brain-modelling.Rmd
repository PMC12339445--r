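---
title: "Whole-brain mean-field modelling of static and dynamic functional connectivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-brain mean-field modelling of static and dynamic functional connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`dmfconn` simulates whole-brain resting-state activity with the reduced
Wong-Wang dynamic mean-field model with excitatory (E) and inhibitory (I)
populations. Each cortical region $i$ carries synaptic gating variables
$S_i^{(E)}, S_i^{(I)} \in [0,1]$ evolving as

$$
I_i^{(E)} = w_E I_0 + w_p J_N S_i^{(E)}
          + G_i J_N \sum_j C_{ij} S_j^{(E)}(t - D_{ij}) - J_i S_i^{(I)},
\qquad
I_i^{(I)} = w_I I_0 + J_N S_i^{(E)} - S_i^{(I)},
$$

$$
r = H(I) = \frac{aI - b}{1 - \exp(-d\,(aI - b))},
\qquad
\frac{dS^{(E)}}{dt} = -\frac{S^{(E)}}{\tau_E} + (1 - S^{(E)})\,\gamma_E\,r^{(E)} + \sigma\nu(t),
\qquad
\frac{dS^{(I)}}{dt} = -\frac{S^{(I)}}{\tau_I} + r^{(I)} + \sigma\nu(t).
$$

$C_{ij}$ is the structural connectome (tract weights), $D_{ij}$ the
conduction delay implied by tract length, and the four free parameters are
the global coupling $G$, the excitatory (NMDA) coupling $J_N$ (nA), the
local feedback inhibition $J_i$ (nA), and the excitatory recurrence $w_p$.
Published versions of these equations circulate with typographic corruption
(dropped minus signs on the decay terms and on the inhibitory drive); we
implement the canonical form above, which is the one whose fixed points and
bifurcation structure match the source model.

Excitatory gating drives the four-state Balloon-Windkessel hemodynamic
model (vasodilatory signal, inflow, venous volume, deoxyhemoglobin), whose
readout $V_0(k_1(1-q) + k_2(1-q/v) + k_3(1-v))$ is sampled every TR to give
simulated BOLD.

### Fixed constants and defaults

All constants are config-overridable; the defaults are the published
values of the source models:

| parameter | default | units | meaning |
|---|---|---|---|
| $a_E, b_E, d_E$ | 310, 125, 0.16 | nC$^{-1}$, Hz, s | E transfer function |
| $a_I, b_I, d_I$ | 615, 177, 0.087 | | I transfer function |
| $\tau_E, \tau_I$ | 0.1, 0.01 | s | NMDA / GABA time constants |
| $\gamma_E$ | 0.641 | – | gating kinetics |
| $I_0$, $w_E$, $w_I$ | 0.382, 1.0, 0.7 | nA, –, – | background drive |
| $\sigma$ | 0.01 | nA | noise amplitude |
| $\kappa, \gamma_f, \tau_h$ | 0.65, 0.41, 0.98 | s$^{-1}$, s$^{-1}$, s | hemodynamics |
| $\alpha, \rho, V_0$ | 0.32, 0.34, 0.02 | – | Grubb exponent, O$_2$ extraction, venous volume |

Integration is Euler-Maruyama at `dt = 1 ms` with independent Gaussian
increments $\sigma\sqrt{dt}\,\mathcal N(0,1)$ per population and region,
gating clipped to $[0,1]$ after each step. Delays use a ring buffer with
`round(length/(speed*dt))` steps per connection; because no conduction
speed is part of the fitted parameter set, the default mode is
"no-delays" (`conduction_speed = Inf`), with finite speeds available for
sensitivity analyses. Initial conditions are $S = 0.001$ plus a seeded
uniform jitter of $10^{-3}$; identical seed and configuration give
bit-identical trajectories (the noise stream is R's RNG).

## FC metrics

Four fitting targets are computed per subject or simulation:

* **sFC** — Pearson correlation of each region pair over the scan,
  Fisher-z transformed ($|r|=1$ clipped at $\mathrm{artanh}(1-10^{-7})$),
  zero diagonal.
* **FCV** — per-edge sample variance of windowed FC over time.
* **TC** — per-node neighborhood persistence of the binarized dynamic
  graph between consecutive windows; isolated-node terms count 0, so the
  metric stays in $[0,1]$ and is monotone in edge persistence.
* **NC** — per-pair count of simultaneous community switches across
  consecutive windows, on seeded per-window Louvain partitions aligned in
  time by greedy maximal-Jaccard label matching (ties toward the smaller
  previous label).

Windows are rectangles convolved with a Gaussian taper ($\sigma$ = 6 s)
and slide in steps of 2 s; the default window length is 60 s. The window
count follows $W = \lfloor (T\,\mathrm{TR} - L)/s \rfloor + 1$. (At the
HCP geometry of 1200 samples, TR 0.72 s, this gives 403 windows; reports
of 420 windows for the same geometry are not reproducible from any natural
reading of the construction, so the geometry is configurable and the count
formula is the documented one.) Binarization keeps the top 10% of
upper-triangle values per window — per window rather than pooled, so the
temporal edge density is constant and TC/NC are not driven by global
amplitude drifts; ties break by value then lexicographic pair order, so
the graph is deterministic.

The fit of a simulation to a subject is the Pearson correlation of each
metric over the strict upper triangle (matrices) or the region vector
(TC). The combined criterion is the Euclidean distance of
$(r_{\mathrm{sFC}}, r_{\mathrm{TC}})$ from the ideal point $(1,1)$ and is
minimized; maximizing the norm of the fit vector instead would reward
large negative correlations.

## Fitting and the multistability screen

A simulation library is built once per connectome — one stochastic
simulation per grid point, with seeds derived from a master seed through a
labelled-counter scheme — and reused across all subjects (fitting never
re-simulates; the package exposes a simulation counter so this contract is
testable). Local parameters $(J_N, J_i, w_p)$ are screened for
multistability first: short noise-free runs from a low ($S = 0.001$) and a
high ($S = 0.9$) initial state across the coupling range, flagged when the
branches' mean excitatory rates differ by more than 1 Hz for at least one
$G$. With the canonical constants an isolated node is monostable; network
bistability emerges when strong feedback inhibition ($J_i \gtrsim 2$ nA)
places the low branch next to a coupling-driven high branch, which is the
regime the desk-scale fitting exercises use.

## Synthetic data

The generator stands in for the empirical inputs with matched geometry:

* **Connectome** — random mirrored centroids in a ~70 mm sphere, lengths =
  Euclidean distances, connection probability $\propto e^{-d/60\,\mathrm{mm}}$
  with a 3x probability/weight boost for a 15% hub fraction, plus a random
  spanning tree so the graph is always connected. Weights are scaled to
  mean row strength 1 (`normalize_coupling`) before simulation so the
  interpretable range of $G$ does not depend on weight units.
* **Parcellation** — balanced assignment to the seven canonical RSN
  labels, alternating hemispheres, centroids mirrored across the midline.
* **Cohort** — per-subject parameters drawn from truncated normals around
  the canonical values, each subject simulated through the forward model
  with a derived seed. Default geometry mirrors HCP-style inputs (TR
  0.72 s; up to 1200 samples at full scale).
* **Planted linear targets** — for calibrating the prediction module;
  coefficients have magnitudes in $[0.5, 1.5]$ (random sign) so each
  planted feature carries a detectable variance share, and noise is scaled
  to hit a nominal population $R^2$ exactly.

Because cohorts come from the pipeline's own forward model, parameter
recovery is a well-posed exercise; what passing recovery tests do *not*
show is robustness to model mismatch (empirical BOLD has hemodynamic,
vascular, and head-motion structure the generator does not emulate).

## What the desk-scale tests do and do not show

The test suite runs everything at desk scale: 8-15 regions, a 5x3x3x3
grid, 60-1200 BOLD samples. Parameter recovery under these conditions
uses a grid straddling the quiet-to-active transition
($G \in \{1.5, 2, 2.6, 3.4, 4.4\}$ at $J_i \approx 2.5$, noise
$\sigma = 0.02$, 1200 samples at TR 0.72 s), where sFC is strongly
coupling-sensitive. Two caveats are documented rather than hidden:

* $G$ and $J_N$ enter the long-range drive as a product, and $J_i$
  partially compensates both; these ridges are intrinsic to the model
  (the same degeneracy underlies the reported non-identifiability of
  $J_i$ and $w_p$), so recovery is asserted up to grid adjacency, not
  exactness, and the $G$ values are spaced geometrically with a ratio
  matching one $J_N$ grid step ($\approx 1.3$), so a one-step ridge
  alias lands on an adjacent $G$ value rather than two steps away.
  Subjects deep in the bistable band can also dwell in one attractor for
  most of a scan and then resemble a neighbouring coupling regime;
  longer scans shrink but do not eliminate this failure mode.
* TC at 15 regions and 10% density rests on ~10 edges per window and is
  an intrinsically noisy estimate; the library therefore uses simulations
  at least as long as the subjects', and the desk binarization density is
  raised to 20% so the mean binarized degree is comparable to the
  empirical 70-region / 10% setting. At full scale (70 regions) the 10%
  default applies unchanged.

## Statistics

* Permutation p-values use the add-one estimator
  $(1 + \#\{|r_{perm}| \ge |r_{obs}|\})/(n_{perm}+1)$, permuting the
  outcome over subjects with one shared stream across features.
* FDR control is Benjamini-Hochberg; it is applied within each
  outcome-by-feature-family block.
* Group contrasts use Welch's $t$ (the two-sample test robust to unequal
  variances); its type-I calibration is part of the test suite.
* Ridge prediction standardizes features and fits PCA inside each
  training fold (minimal components exceeding 90% explained variance for
  edge features; all components for node features), selects the penalty
  from 100 log-spaced values in $[0.01, 100]$ by inner 5-fold x 2-repeat
  CV, and reports held-out $R^2 = 1 - SSE/SST$ (negative when worse than
  the constant model) as mean ± SEM over the 10 outer evaluations. The
  ridge solve is the closed-form normal equation, which exposes the
  penalty grid exactly. Permutation importance shuffles original
  (pre-PCA) columns through the frozen pipeline; since the frozen
  pipeline is linear, the shuffle only shifts predictions along that
  column's weight, which the implementation exploits.
* Spin tests rotate the centroid sphere (uniform SO(3) via QR), apply the
  mirrored rotation to the left hemisphere, reassign regions to their
  nearest rotated neighbour within hemisphere, and use the add-one
  two-sided p-value. Duplicated nearest neighbours are possible on small
  parcellations; the null preserves the spatial autocorrelation structure
  rather than the exact value multiset.

## Perturbation analysis

The perturbation module refits the group-average subject with the
combined criterion, then re-simulates with $G$ overridden in one region
at a time (the override enters only that region's long-range input term).
Deltas are reported as default minus perturbed — positive values mean the
perturbation worsened the fit — with one shared noise seed between the
default and every perturbed run, so a perturbation at the default $G$
yields deltas that are exactly zero and all other deltas reflect the
parameter change alone. Efficiency is computed on the positive part of
the simulated correlation matrix (not Fisher-z, whose unbounded diagonal
neighbourhood would distort the inverse-distance weighting).

## Numerical choices

* Transfer function: the removable singularity at $aI = b$ is evaluated
  by the series $1/d\,(1 + v/2 + v^2/12 - v^4/720)$ for $|v| < 10^{-4}$,
  accurate to machine precision, and by an `expm1` form elsewhere.
* Robust connectome rescaling subtracts the median of the nonzero entries
  and divides by their IQR (absent connections are not statistics),
  clips negative scaled values to 0 — coupling must stay non-negative, so
  the weakest connections sparsify — and rounds to the nearest even
  integer with half-way cases rounding up.
* Element-wise connectome averaging sums sorted values per entry, making
  the group average exactly invariant to subject order.
* Degenerate inputs fail loudly with classed conditions
  (`dmfconn_format_error`, `dmfconn_validation_error`,
  `dmfconn_degenerate_error`, `dmfconn_integration_error`) rather than
  propagating NaN; the one deliberate softening is inside the library
  scan, where a degenerate metric on a single grid point scores `NA` for
  that criterion instead of aborting the whole grid search.

## Limitations

* A single neural-mass family and a single stochastic integrator
  (Euler-Maruyama); no FIC auto-tuning of $J_i$.
* TC/NC at very small parcellations are noisy; see the density note
  above.
* The synthetic connectome reproduces hubness and distance decay, not
  tractography statistics.
* Gene-expression and enrichment analyses around the perturbation maps
  are out of scope; `correlate_maps` accepts any user-supplied region
  map so such maps can be plugged in externally.
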