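---
title: "Reward-modulated cell-assembly formation in a six-area spiking cortical network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reward-modulated cell-assembly formation in a six-area spiking cortical network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(canet)
```

## The model

`canet` simulates a brain-constrained network of six cortical areas
implicated in hand/finger action: three frontal "motor" areas -- primary
motor (M1), premotor (PM) and prefrontal (PF) cortex -- and three parietal
"somatosensory" areas -- primary somatosensory (S1), somatosensory
association (SA) and posterior parietal association (PA) cortex. Each area
is a 25 x 25 grid of cortical columns; each column holds one excitatory
spiking cell and one graded inhibitory cell, 7,500 cells in total.
Between-area projections exist only where white-matter tracts are
documented between the corresponding regions: twelve reciprocal links
(`area_graph()`), comprising next-neighbour links within each system,
"jumping" links (PF-M1, PA-S1), and long-distance links bridging the two
systems (M1-S1, M1-SA, PM-S1, PM-SA, PA-PM, PA-PF).

### Cell dynamics

Excitatory cells are leaky integrate-and-fire units with adaptation. The
membrane potential follows

$$\tau\,\dot V(x,t) = -V(x,t) + k_1 V_{in}(x,t) + k_2\,\eta(x,t),$$

integrated by explicit Euler steps of $\Delta t = 0.5$ (arbitrary time
units), with $\tau = 2.5$ for excitatory and $5$ for inhibitory cells.
$\eta$ is uniform white noise on $[-0.5, 0.5]$, drawn independently per
cell and step, modelling spontaneous baseline firing; $k_2 = N\sqrt{48}$
with $N = 15$ for excitatory cells and $0$ for inhibitory cells. The net
input $V_{in}$ sums a constant baseline ($V_b = 0$), between-area weighted
spikes (gain $k_{ffb} = 500$), within-area weighted spikes (gain
$k_{rec} = 500$), the summed output of the local inhibitory surround
(gain $k_{inh} = 500$, fixed unit weights), and area-level global
inhibition (gain $k_G = 95$).

A cell spikes when $V - \alpha\,\omega > thresh$ with $thresh = 0.18$ and
adaptation strength $\alpha = 7$; there is no membrane reset --
refractoriness comes entirely from the adaptation estimate $\omega$, a
low-pass filter of the cell's own spikes with time constant
$\tau_A = 10$. A second, slower filter $\omega_E$ ($\tau_{Favg} = 30$)
estimates the mean firing rate for the plasticity rule. Inhibitory cells
output their rectified membrane potential. Per area, a single slow unit
($\tau_S = 12$) tracks total excitatory firing and inhibits all the
area's excitatory cells proportionally, keeping activity within
physiological bounds.

### Plasticity

Excitatory-to-excitatory synapses follow the Artola-Bröcher-Singer (ABS)
rule: given sufficient presynaptic activity
($\omega_E \ge \theta_{pre} = 0.05$), the postsynaptic potential decides
between potentiation ($V \ge \theta_+$) and depression
($\theta_- \le V < \theta_+$, with $\theta_- = 0.14$); a strongly
depolarized postsynaptic cell with a near-silent presynaptic partner also
depresses. Updates apply only on steps where the pre- or postsynaptic
cell spikes. The novel element is a binary, globally broadcast
dopamine-like reward signal $R$ that (i) boosts the weight change by 50%,
$\Delta w = \Delta w_{base}(1 + 0.5\,R)$ with
$\Delta w_{base} = 0.001$, and (ii) lowers the LTP threshold from
$\theta_{+max} = 0.20$ to $\theta_{+min} = 0.15$, enlarging the
potentiation regime. With $R = 0$ the rule is plain Hebbian ABS learning.

### The two-phase protocol

**Phase I (exploration).** Twelve "motor-haptic" pattern pairs -- 19
cells in M1 and 19 in S1 each, disjoint across patterns by default --
are each presented 1,000 times at full scale (clamped for 16 steps at
amplitude 500, order randomized), with reward off. Hebbian learning binds
each pair into a distributed cell-assembly (CA) circuit spanning all six
areas.

**Measurement.** With learning frozen ($\Delta w_{base} = 0$) the network
runs on noise alone; a CA *ignites* when at least 50% of its member
cells are simultaneously active, and an ignition *episode* lasts from the
first assembly crossing the threshold until all have fallen below it. At
full scale 2,000 episodes are recorded per measurement.

**Phase II (exploitation).** Assemblies are ranked by spontaneous
ignition frequency (size breaking ties), split into two
probability-balanced groups of six by the rank-interleaving pattern
A B B A | B A A B | A B B A, and two identical twins of the trained
network run with complementary reward assignments: whenever a rewarded
assembly is ignited, $R = 1$ network-wide; it resets as soon as all
rewarded assemblies fall below threshold. Each twin runs until 9,000
ignitions (full scale) and is then measured again. Rewarded assemblies
grow and ignite more often; unrewarded ones shrink -- the network
acquires a reward-seeking ignition bias.

### Analysis pipeline

Per network and condition (Pre-reward, Rewarded, Unrewarded), ignition
frequency, mean ignition duration and CA size are computed after
excluding every episode that contains a co-activation (two assemblies
simultaneously at threshold), since co-activations can smear reward
across groups. Networks whose co-activation rate exceeds the upper Tukey
fence (Q3 + 1.5 IQR, per condition column, type-7 quartiles) are excluded
entirely. Group-level values feed one-tailed paired t-tests and a
2 (group) x 3 (reward condition) repeated-measures ANOVA with Mauchly's
sphericity test, Greenhouse-Geisser correction and Bonferroni post hocs
(`rm_anova_2x3()`, validated against `car::Anova()` to 1e-6).

## Design choices in the open corners

Several quantities the model needs are not fixed by the standard
parameter set; `canet` makes one documented choice for each and exposes
it in `model_params()`.

* **Connection kernel** (`p0_exc = 0.5`, `sigma_exc = 9.5`; `p0_inh = 1`,
  `sigma_inh = 1.25`). Links are created with probability
  $\min(1, p_0 e^{-d^2/2\sigma^2})$ inside the neighbourhood square
  (19 for excitatory, 5 for inhibitory projections), clipped at grid
  borders (cortical patches, not tori), with the identity map as the
  topographic correspondence. The kernel peak and width are calibration
  constants chosen so that Phase I produces stable, input-specific,
  igniting assemblies; they are not empirical claims. A narrow kernel
  ($\sigma \approx$ neighbourhood/4) links randomly placed 19-cell
  patterns too sparsely for reverberation, hence the grid-scale width.
* **Stimulation pathway** (`drive_through_k1 = FALSE`). The clamping
  amplitude (500) enters the membrane equation directly rather than
  through the $k_1 = 0.01$ input scaling. Passed through $k_1$ the drive
  (5) sits an order of magnitude below the standing global-inhibition
  input of the spontaneously active network, clamped cells never fire,
  and no associative learning can occur. A companion switch
  (`noise_through_k1`) exists for the noise term; scaling the noise down
  by $k_1$ collapses the per-cell noise below the common-mode dynamics
  and the network synchronizes into global avalanches, so the default
  keeps the standard amplitude.
* **Local inhibitory circuit.** The local inhibitory input of the membrane
  equation sums over the inhibitory cells of the 5 x 5 surround at the fixed
  unlearned weight 1 (only excitatory-to-excitatory synapses are
  plastic); each column's inhibitory cell is in turn driven by its own
  excitatory twin (`w_ei = 1`). This surround arrangement implements the
  local winner-take-all competition that keeps assemblies input-specific
  and prevents locally clumped runaway groups.
* **Weight ceiling** (`w_cap = 0.8`). The rule has no intrinsic upper
  bound; the ceiling sets the strength of a fully trained synapse and
  thereby the spontaneous ignition rate. Below ~0.5 trained assemblies
  hardly ever ignite; well above 1 training destabilizes into
  self-sustaining attractors; 0.8 yields regular episodic ignitions of
  all twelve assemblies.
* **Plasticity window** (`learn_in_isi = FALSE`). The ABS rule applies
  during the 16-step stimulation window; the inter-stimulus interval
  only decays activity back to baseline. With interval plasticity
  enabled, spontaneous co-firing between presentations strengthens
  arbitrary links and training destabilizes after a few hundred
  presentations; restricting learning to the stimulus-driven window is
  stable and preserves input specificity.
* **Inter-stimulus interval.** "Activity returns to baseline" is
  operationalized as every area's summed excitatory spikes staying below
  `baseline_tol = 50` for 10 consecutive steps, hard-capped at 100 steps.
* **Per-cell activity criterion.** For instantaneous CA activity a member
  counts as active when its fast rate estimate $\omega$ exceeds
  `activity_floor = 0.04`. Spontaneous ignitions are brief volleys in
  which members spike once or twice; a single spike lifts $\omega$ to
  $dt/\tau_A = 0.05$, so the floor is set just below that.
* **Responsiveness measurement.** A cell's response to a pattern is the
  baseline-corrected peak of $\omega_E$ during the 16-step presentation
  (its pre-stimulus value subtracted). Without the correction, cells that
  merely happened to be noise-active at stimulus onset enter the circuit.
  Membership thresholds at $\gamma = 0.5$ of the per-area maximum,
  separately per input and area, and an area only contributes members
  when its maximal response exceeds `response_floor = 0.125` -- the rate
  increase of a cell firing throughout half the window. Without the
  floor, areas receiving no genuine stimulus-locked drive contribute
  noise cells (the per-area $\gamma$ rule keys on a noise maximum) that
  dilute the assembly below the 50% ignition threshold.
* **Ignition bookkeeping.** Threshold comparison is inclusive at onset
  ("reached 50%") and strict at offset; Phase II counts individual CA
  ignition onsets (not episodes) toward its stop criterion, and reward
  during co-ignitions stays on (contaminated episodes are excluded from
  analysis, not from learning).
* **Reward-gating membership** is frozen at the end-of-Phase-I
  identification; circuits are re-identified only at the post-reward
  measurement point.

## What the synthetic generator emulates -- and what it does not

All inputs are synthesized: the pattern pairs stand in for correlated
motor and haptic activity during infant motor babbling, and the uniform
membrane noise for spontaneous baseline firing. The generator reproduces
the study conditions (12 pairs of 19 cells, disjoint within each area;
seeded connectivity and weights; noise in every cell at every step). It
does not emulate muscles, objects, visual input, delayed reward, graded
dopamine concentrations, or any environment -- action execution and its
sensory consequence are both represented as clamped cortical patterns,
so passing tests demonstrate the circuit-level mechanism, not behaviour
of an embodied agent.

## Numerical choices

Double precision throughout (long runs accumulate low-pass state); fully
synchronous updates (all step-$t$ inputs use step $t-1$ outputs), which
is the only scheme consistent with area-parallel Euler integration and
bit-reproducibility; plasticity evaluates the step-$t$ values of
$\omega_E$ (presynaptic) and $V$ (postsynaptic) after the state update,
with the instantaneous reward level of the same step and no smoothing.
One master seed expands into named sub-streams (`derive_seed()`:
connectivity, patterns, per-phase noise) so each stage can be replayed
independently; the compiled stepper and the pure-R reference stepper
consume identical noise streams (one uniform per excitatory cell per
step, in cell order) and agree to 1e-9 over tested trajectories. The
degenerate all-equal ANOVA input returns $F = 0$, $p = 1$; quartiles use
R's default type-7 definition.

## Problem sizes

Full scale matches the study design: 18 networks, 1,000 presentations
per pair, 9,000 Phase II ignitions per twin, 2,000 measurement episodes.
The package's default desk-scale profile (`experiment_config()`: 3
networks, 250 presentations, 1,500 ignitions, 300 episodes) preserves
the protocol's shape at workstation runtimes; the test suite uses still
smaller per-seed runs chosen to keep the full suite in the tens of
minutes while leaving the directional reward effect detectable. At
reduced scale the absolute assembly sizes and ignition statistics sit
below their full-scale values; only directions and counts are
interpreted.

## Known limitations

Reward is binary and immediate (no eligibility traces, no distal-reward
credit assignment, no inverted-U high-dopamine regime); inhibitory
synapses are static; there are no conduction delays; assembly membership
is spatially unresolved (no topography analysis of member locations); and
the desk-scale statistics are illustrative -- the full 15-subject
inferential battery requires full-scale runs.

Two quantitative limitations of the calibrated desk-scale regime deserve
emphasis. First, at the standard noise and inhibition levels the standing
global inhibition of the spontaneously active network keeps weakly driven
cells silent, so trained assemblies remain essentially the union of the
two clamped input patterns (~38-50 cells in M1 and S1) rather than
spreading into the intermediate areas; the documented between-area
projections still carry the M1-S1 binding. Second, spontaneous ignitions
here are brief volleys (3-6 steps), shorter than the slow rate filter
$\tau_{Favg} = 30$ that gates plasticity. During such a volley a member's
$\omega_E$ stays below $\theta_{pre}$, so ignition-driven potentiation --
and with it the reward signal's 50% boost -- engages only marginally,
while the slow background depression of free running acts on every step.
As a consequence, Phase II at desk scale erodes assemblies faster than
reward can differentiate them, and the rewarded-versus-unrewarded
divergence in size and ignition frequency, clearly expressed at full
scale in sustained-reverberation regimes, is near the noise floor here.
The acceptance tests state this expectation as directional checks and
report the measured outcome rather than adjusting it.
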