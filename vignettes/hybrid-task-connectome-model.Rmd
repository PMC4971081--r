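---
title: "A hybrid task-network / connectome model of visual working memory"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A hybrid task-network / connectome model of visual working memory}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(hybridbrain)
```

## The model

`hybridbrain` simulates a delayed match-to-sample (DMS) visual short-term
memory task inside a whole-brain network.  Two kinds of dynamical units
coexist:

**Connectome nodes.** Every region of a structural connectome is a classical
Wilson–Cowan excitatory/inhibitory population pair,

$$\dot E_i = \tfrac{1}{\tau_E}\!\left[-E_i + (k_E - r_E E_i)\,
  S_E\!\big(\alpha_E(c_{EE}E_i - c_{IE}I_i - \theta_E + \Gamma_i)\big)\right],$$

with the analogous inhibitory equation using $(c_{EI}E_i - c_{II}I_i -
\theta_I + \Gamma_i)$, sigmoid $S(f) = c/(1 + e^{-a(f-b)})$, and the
long-range coupling
$\Gamma_i = a_\Gamma \sum_k u_{ik}\,E_k(t - d_{ik})$ over the structural
weights $u_{ik}$, with conduction delays $d_{ik}$ from tract length over
conduction speed.  Nodes are integrated by stochastic Euler with additive
Gaussian noise; they are the model's biologically structured noise source.
The noise amplitude (0.10 per $\sqrt{\text{ms}}$) is deliberately vigorous:
the non-task nodes inside each imaging ROI must dominate the region's
synaptic-activity fluctuations outside stimulus-driven episodes, which is
what makes stimulus structure clearly visible in V1's integrated synaptic
activity but buried in noise elsewhere, and keeps within-condition
correlations in the moderate range characteristic of regional
functional-connectivity analyses.  With a weak noise source the task
modules' synaptic inputs would deterministically track their afferents and
all correlations would saturate near one.
The optional surface-level local-neighbourhood coupling of mesh-based
simulators is not part of this model.

**Task units.** The task network comprises ten modules of 81 units
(9&times;9 grids) representing cortical columns along the ventral visual
pathway — orientation channels V1h/V1v, extrastriate V4h/V4c/V4v,
inferotemporal IT — and four prefrontal populations in the Funahashi
typology: stimulus-sensitive FS, delay-active D1, stimulus-and-delay D2,
and response FR.  Each unit is a *modified* Wilson–Cowan pair,

$$\dot E_i = \Delta\,\sigma\!\big(K_E[w_{EE}E_i + w_{IE}I_i + in_i^E -
  \phi_E + N(t)]\big) - \delta E_i,$$

with the unit logistic $\sigma$, no inhibitory self-connection, and input
sums $in_i^E = \sum_j w^E_{ji}E_j + \sum_j w^I_{ji}I_j + \sum_j c_{ji}
z_{ji} C_j + \text{drives}$; connectome afferents ($C_j$, with coupling
samples $c_{ji}$ and structural weights $z_{ji}$) reach excitatory elements
only.  With $\Delta = \delta$ the activities live in $[0,1]$ (they are also
clamped there, the display convention for firing-rate traces).

## Embedding

`build_embedding()` follows a four-step procedure: each module carries a
hypothesized Talairach coordinate; the nearest connectome node becomes its
*host*; every node with a connection into the host is wired to all 81 units,
with per-(afferent, unit) couplings drawn from a Gaussian of mean $G/81$
(the long-range coupling constant divided by the module size; s.d. 10% of
the mean, clipped at zero); and reciprocal feedback connections run from the
module's excitatory units back to exactly those afferents at $G z / 81$ per
unit, so the module aggregate acts like one node of equivalent mean
activity.  Embedding only *adds* connections: all original connectome edges
are preserved bit-for-bit, and the host stays an active node (its activity
is the "background noise" trace plotted alongside each module).

Because $a_\Gamma$ is not separately constrained here, the package defaults
to $a_\Gamma = G$: one global constant scales node→node, node→module and
module→node coupling.  Both choices are config-overridable.

The ten modules are placed at seven anatomical sites; V1 and V4
sub-populations (and the prefrontal populations other than D1) sit at
illustrative adjacent coordinates, so on a coarse substrate two targets can
resolve to the same node.  The contract treats that as an error
(`host_collision = "error"`); the pipeline default `"next"` assigns the
next-nearest unclaimed node with a warning, which is the only practical
choice on synthetic substrates of a few hundred nodes.

## The task circuit

The wiring that performs the task (all weights in
`default_weight_set()`, overridable via `weights:` config entries):

* **V1 → V4**: 3&times;3 receptive-field convergence per orientation
  channel; V4c pools both channels with a higher threshold and acts as a
  corner detector.
* **V4 → IT**: the three channels are pooled cell-wise and scattered over
  the IT grid by a seed-fixed permutation.  The IT code is distributed (no
  retinotopy) yet preserves pattern identity exactly.  A random fan-in
  projection was rejected during design: with $P$ the probability a random
  IT unit is active, two *unrelated* shapes share $\approx 81 P^2$ active
  units in expectation, an irreducible overlap floor that defeats a 2-unit
  response criterion; the permutation code makes IT overlap equal to the
  (controllable) V4 footprint overlap.
* **IT → FS** and **IT → D2**: grid-aligned copies.  D2's threshold sits
  above the IT drive alone, so D2 ignites only when the attention/task
  control input (applied to all D2 units) is at task level (0.24–0.34),
  not at the passive-viewing level (0.05).
* **D1 ↔ D2**: a recurrent loop holding the sample across the delay.  The
  protection of the stored trace is a spread projection from D1 onto *all*
  D2 inhibitory elements with high gain: any stored trace saturates D2's
  within-unit inhibition (D2 carries a stronger $w_{IE}$ than other
  modules), and only units with grid-aligned D1 support can overcome it.  A
  mismatching probe therefore cannot overwrite the memory, while an empty
  memory leaves ignition free.
* **FR ← FS + D1**: the response module is a coincidence detector between
  the current stimulus identity (FS) and the held trace (D1); its threshold
  is crossed only when both drives land on the same unit, i.e. on a match.
  Wiring FR from D1/D2 alone was tried first and rejected: during the delay
  D1 and D2 are both high on the memorized units, making the delay state
  indistinguishable from a match.
* **D2 → IT**: weak feedback, closing the prefrontal-temporal loop.

Two phenomenological consequences are documented limitations: D1 here is
stimulus-and-delay active rather than delay-only (a delay-only D1 required
an FS→D1 suppression that erased the memory at probe onset), and FR also
fires during an attended sample presentation (scoring reads only the probe
window, so neither affects task performance).

The attention drive follows the trial, not the block: it is applied from
sample onset to probe offset and falls back to the passive level during the
inter-trial interval, letting the delay attractor collapse and clearing the
memory before the next trial.

## Stimuli and simulated subjects

Stimuli are axis-aligned stroke shapes on the 9&times;9 grid, split into
horizontal/vertical orientation channels.  The library holds ten shapes laid
out in distinct grid regions; `shape_footprint()` predicts each shape's
extrastriate band, and the design samples mismatch probes only from shapes
whose footprints overlap the sample's by at most one cell — a
discriminability-controlled stimulus set.  Control (passive-viewing) trials
use degraded shapes: each active cell is retained with probability 0.5.

A simulated subject multiplies every feed-forward template by an independent
uniform draw in [0.95, 1]; recurrent and feedback templates are untouched.
`generate_subjects()` runs the inclusion loop: candidates perform the full
36-trial experiment (12 alternating blocks of 3 trials, 16.5 s per block,
198 s total; attention evenly spaced over 0.24–0.34 across DMS blocks) and
are retained while their DMS accuracy exceeds 60%, a response being ≥ 2 FR
units strictly above 0.7 during the 1-s probe window.  Under the default
noise ($N(t)$ zero-mean Gaussian, s.d. 0.025 per unit per 5-ms step, shared
by a unit's two elements) accuracies land at 85–95%: errors are mostly
false alarms on residually overlapping mismatch pairs, plus occasional
noise-driven responses.  Performance degrades monotonically as the noise
amplitude grows, which the test suite checks on a shortened design.

## Forward models

**Integrated synaptic activity (ISA).**  Per unit and step, $IN_i = w_{EE}
E_i + w_{EI} E_i + |w_{IE} I_i| + \sum_k |w_{ki}| E_k$ over all afferents
and drives; connectome nodes use the analogous sum over their own
within-unit weights, with the (nonnegative) coupling input counted toward
both elements.  ISA is summed over each ROI and over 50-ms windows.  An ROI
is one embedded module plus its host and the five nearest non-host nodes;
region-level ROIs merge co-located populations (V1h+V1v, V4h/c/v) the way a
scanner voxel would.

**Balloon–Windkessel BOLD.**  The ROI's ISA, scaled to zero mean and unit
range, drives the standard hemodynamic state equations from rest
$(s,f,v,q) = (0,1,1,1)$, with readout $y = V_0(k_1(1-q) + k_2(1-q/v) +
k_3(1-v))$, $k_1 = 4.3\,\vartheta_0 E_0 T_E$, $k_2 = \varepsilon r_0 E_0
T_E$, $k_3 = 1-\varepsilon$.  Constants follow the Friston/Obata family at
1.5 T ($V_0 = 0.02$, $E_0 = 0.34$, $T_E = 40$ ms, $\varepsilon = 1.43$,
$r_0 = 25\,s^{-1}$, $\vartheta_0 = 40.3\,s^{-1}$, $\alpha = 0.32$), with
the three time constants at the slow end of the published ranges
($\tau_s = 2.0$ s, $\tau_f = 4.0$ s, $\tau_0 = 2.0$ s) so that the impulse
response peaks ≈ 4.5 s after a stimulus, the canonical 4–6 s hemodynamic
delay.  Integration is explicit Euler at 5 ms (10 sub-steps per ISA bin;
halving the step changes the output by < 0.1% RMS), and the series is
decimated to TR = 2 s with no anti-alias filter, matching plain
downsampling.

The ISA→drive scaling is a design choice: the model never states a unit
conversion between synaptic activity and the vasodilatory drive, and
zero-mean/unit-range keeps the efficacy parameter acting on a bounded
signal regardless of ROI size.

## Analyses

Functional connectivity is the Pearson correlation of two regional series
over the samples falling in one condition's blocks (no hemodynamic lag by
default; a lag in samples is configurable).  Group averages pass through
Fisher's Z; condition differences use the closed-form paired t test with
n−1 degrees of freedom, uncorrected, as in the source analyses.  The
contralateral-IT control region is the connectome node nearest the mirror
image (x negated) of the IT host plus its five nearest neighbours — pure
noise, so its FC with IT hovers near zero.  Block signal change is the mean
BOLD at the 4th–6th TR after each block onset, expressed as percent change
about the series mean on a unit baseline (the affine convention cancels in
DMS−CTL differences).  BOLD-level FC uses the raw TR series, not percent
change.

## Numerical choices

* Both subsystems step at 5 ms and exchange activities every step.
* Delay discretization: nearest step, with a floor of one step when the
  conduction speed is finite (explicit-Euler causality); `speed = Inf`
  reproduces the undelayed coupling exactly.
* Connectome noise enters as an additive Euler–Maruyama term
  ($\sqrt{dt}\,\sigma$); task-unit noise enters inside the sigmoid argument,
  as the equations place it.
* Task-unit activities are clamped to [0, 1]; node activities are left to
  their own (bounded) dynamics.
* Every stochastic component takes an explicit seed; a run is bit-for-bit
  reproducible from (connectome seed, embedding seed, design seed, subject
  seed, noise seed).

## The synthetic substrate

`synthesize_connectome()` emulates the statistical shape of a DSI-derived
human connectome: ~1000 nodes on a two-hemisphere ellipsoidal shell
(default 998, density 0.03), symmetric nonnegative weights whose
probability and magnitude decay with distance (40-mm decay length,
log-normal magnitude jitter), tract lengths equal to Euclidean distance,
and mirror-paired nodes so every region has a contralateral homologue.  It
does **not** reproduce hemispheric asymmetries, the lobe-level community
structure, geodesic (curved) fibre lengths, or the heavy inter-subject
variability of real tractography — so passing tests show the *method*
behaves correctly on a realistic substrate class, not that any particular
empirical connectome would yield the same numbers.

The package's own analyses (test suite and the acceptance script) run on
128-node substrates at density 0.1 with 5–6 retained subjects — sizes
chosen so a full study executes in minutes on one core while every
qualitative contrast (delay-period memory, match-specific responses,
DMS &gt; CTL signal change and IT-seeded FC, and the flat FC of the
connectome-only stimulation control) is comfortably resolved.  The
properties checked are scale-free; the reduced sizes are stated here as the
package's choice of desk-scale study conditions.

## Known limitations

* The prefrontal typology is partial: D1 is not delay-only, and FR fires
  during attended samples (see above).
* Simulated accuracy (85–95%) sits above the 61–83% range reported for
  comparable subject cohorts; the inclusion bound and all directional
  contrasts are insensitive to this.
* The degraded-stimulus control nearly silences V4/IT feed-forward drive,
  so control-condition object responses are weaker than the task-level
  attention account alone would predict.
* No EEG/MEG forward model, no spiking dynamics, no plasticity, and no
  per-subject structural variability (all subjects share one connectome, as
  in the source design).
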