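---
title: "Modeling spine calcium: mechanistic model, surrogate, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling spine calcium: mechanistic model, surrogate, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spinecal)
```

# The system being modeled

A glutamatergic spine on a CA1 pyramidal neuron keeps its free calcium near
50 nM at rest and transiently raises it — by one to two orders of magnitude —
in response to synaptic and somatic activity. Two influx routes dominate:
NMDA receptors in the postsynaptic density (PSD), gated jointly by glutamate
and by relief of their voltage-dependent magnesium block, and low-voltage
activated T-type calcium channels opened by backpropagating action
potentials (bAPs). Extrusion is carried by the plasma-membrane calcium
pump (PMCA; high affinity, low capacity) and the sodium-calcium exchanger
(NCX; low affinity, steeply recruited). Most entering calcium never stays
free: calmodulin, calbindin-D28k and a lumped pool of other calcium-binding
proteins (CBP) bind the bulk of it, and a SERCA/ryanodine-receptor ER store
exchanges calcium with the cytosol in the ~19% of spines that contain ER.

`spinecal` implements this system twice:

1. a **mechanistic model** — a two-compartment (PSD + spine head) ODE
   system coupling all of the above, and
2. an **input-output surrogate** — a two-input, third-order Volterra series
   on orthonormal Laguerre bases, trained on the mechanistic model, that
   maps the spine's two observable drives (membrane potential and total
   NMDAr conductance) directly to spine calcium at a fraction of the cost.

# Mechanistic model

## Compartments and diffusion

The PSD is a very small sub-compartment (0.0032 µm³ against the 0.1 µm³
spine head) that receives the NMDAr calcium current and exchanges calcium
with the head by first-order diffusion,

$$\frac{d[\mathrm{Ca}]_{spine}}{dt}\Big|_{diff}
  = \frac{DA}{d\,V_{spine}}\left([\mathrm{Ca}]_{PSD}-[\mathrm{Ca}]_{spine}\right),$$

with the mirrored term (scaled by $V_{PSD}$) on the PSD side, so diffusion
conserves calcium mass exactly. The interface area $A = 0.132$ µm² is the
PSD area; the midpoint distance $d$ (0.24 µm) and the diffusion coefficient
$D$ (0.22 µm²/ms, a typical cytosolic free-calcium value) are not
independently measurable here and are exposed in the configuration.
Exchange with the dendrite is omitted: spine necks isolate the head well
enough that dendritic flux is a sub-percent effect. No spine-to-dendrite
coupling means simulations say nothing about dendritic calcium.

## NMDA receptor pathway

Receptor gating is an 8-state kinetic scheme (unliganded, mono- and
di-liganded, two desensitized branches plus a single-liganded desensitized
state, a pre-open intermediate, open), shipped as an editable edge list
(`inst/extdata/nmdar_rates.tsv`). Rate constants follow the GluN1/GluN2A
single-channel literature; the open-state closing rate is set so the scheme
expresses that receptor's hallmark synaptic behavior — peak open
probability ~0.17 for a 1 mM × 1 ms glutamate pulse and deactivation
$\tau \approx 50$ ms. A presynaptic event is a square glutamate pulse
(1 mM, 1 ms; both configurable).

The open-channel conductance interpolates between the one- and
two-glutamate conductances (40 and 247 pS) with a logistic voltage
dependence, and the magnesium block multiplies it by a Boltzmann factor
(K₀ = 3.57 mM, electrical distance δ = 0.8): ~94% blocked at −65 mV, mostly
relieved near 0 mV. The calcium current is

$$I_{NMDA} = f_{Ca}\, s\; g_{NMDA}\, n_{NMDA}\; V_{Ca},
\qquad V_{Ca} = -\frac{RT}{2F}\log_{10}\frac{[\mathrm{Ca}]_o}{[\mathrm{Ca}]_{spine}},$$

with $f_{Ca} = 0.11$ the calcium fraction of the NMDAr current and
$n_{NMDA} = 20$ receptors. $V_{Ca}$ deliberately uses a base-10 logarithm
without the ln(10) factor: that is the only reading that reproduces the
model's own anchor points (−60 mV at 50 nM, −30 mV at 10 µM with 2 mM
external calcium at 299.5 K), and it is applied to the *spine* (not PSD)
concentration, whose tiny volume would otherwise make the driving force
erratic. The single dimensionless factor $s$ (`ca_scale`, 1.199) is the
model's one NMDA-side calibration constant, fixed once so that a lone
presynaptic event at rest peaks at 0.9 µM — the amplitude imaging studies
report for subthreshold synaptic transients.

## T-type channel pathway

A bAP arriving at the spine opens T-type channels
($I = g\,m^2 h\, f_{drive}$, 5 channels × 7.5 pS per event). Gating uses
the CA1 T-type rate functions of the Jaffe/Poirazi lineage and the
concentration-dependent Goldman–Hodgkin–Katz driving term, both read from
`inst/extdata/vdcc_gating.tsv`. The bAP itself is a peak-normalized
difference of exponentials (rise 0.6 ms, decay 8 ms) scaled by a somatic
amplitude (75 mV) and a distance attenuation factor (0.7, i.e. ~30%
attenuation, matching a synapse ~150 µm from the soma;
`bap_attenuation()` provides a qualitative distance map that decays to
near zero beyond ~300 µm). Waveform parameters are the second and last
calibration: they were fixed once so a lone bAP yields a ~700 nM transient
with a fitted decay constant of ~37 ms. Everything else the model
produces — including the ~9 µM pre+AP response and the shape of the
pre/post interval curve — is emergent.

On decay metrics: the transient is distinctly non-exponential (buffers keep
absorbing calcium after the peak, then release it slowly), so "the" decay
time depends on convention. `decay_time()` offers the 1/e time (~15 ms
here) and a single-exponential fit through the first two e-folds (~37 ms);
the latter is what the package quotes for "decay ~30 ms"-style comparisons.

## Extrusion and the resting fixed point

Both pumps are Hill current sources:
PMCA with $I_{max} = 0.25$ pA, $K = 1$ µM, $h = 2$; NCX with
$h = 5$, $K = 1.5$ µM and $I_{max} = g_{NaCa}\,|V_{Na,Ca}|$, where
$V_{Na,Ca} = (RT/F)(3\ln([\mathrm{Na}]_o/[\mathrm{Na}]_i) -
\ln([\mathrm{Ca}]_o/[\mathrm{Ca}]_i))$ and $g_{NaCa} = 0.0117$ pS. Two
printed-value discrepancies in the source literature are resolved in favor
of the majority/source-consistent readings (PMCA $K$ = 1 µM rather than
0.1 µM; $g_{NaCa}$ = 0.0117 rather than 0.117 pS); both alternatives are a
constructor argument away.

Pure efflux would drain the spine to zero, so the model adds a constant
leak influx solved numerically at build time (`resting_leak_rate()`) to
make 50 nM an *exact* fixed point of the fully assembled system — pumps,
resting T-type window current and ER store included. An unstimulated
simulation therefore stays at 50 nM to solver precision, which the tests
assert.

## Buffers and the ER store

Calmodulin is modeled as its Hill parameters state: one cooperative step
binding three calcium ions (total 10 µM, $k_f = 10^8$ mM⁻³ms⁻¹ — reading
the tabulated "10e7" literally — and $k_r = 10$ ms⁻¹). CBP is 1:1
mass action (0.8 mM, 247 mM⁻¹ms⁻¹ on, 4 ms⁻¹ off, so $K_d \approx 16$ µM).
Calbindin is a 9-state occupancy lattice over two independent site classes
(2 high-affinity + 2 medium-affinity sites, per-site rates from the
Nägerl/Bartol literature, file-configurable); its total, 45 µM, is the
standard spine value. The ER store couples a 2-state SERCA pump (binding
two Ca per cycle) and a ryanodine receptor whose opening rate scales with
the fourth power of cytosolic calcium (calcium-induced calcium release),
against a fixed 250 µM lumen. Store parameter defaults are chosen so the
store is a modest contributor, consistent with a model whose single-event
responses are channel- and pump-dominated; `er_store_params(enabled =
FALSE)` removes it, reflecting that most spines lack ER.

A consequence worth stating plainly: with these printed buffer parameters,
the equilibrium bound fraction of spine calcium at 50 nM is ~99.8%
(CBP alone contributes 98.0%), not the ~95% quoted in the experimental
literature. No non-negative calbindin concentration can bring the printed
CBP pool below 98%, so the package reports the number its parameters imply
rather than adjusting unrelated constants to meet the quote.

## What the event generator emulates — and what it does not

Stimulation is specified as event trains: presynaptic glutamate release
times and postsynaptic spike times. `poisson_train()` draws homogeneous
Poisson trains (seeded, reproducible); the Izhikevich point neuron
(`izhikevich_run()`) can elicit postsynaptic spikes from synaptic drive
when a protocol calls for an evoked AP, and every spike reaches the spine
as the parametric bAP waveform. This reproduces the *statistics* of the
published stimulation protocols (2 and 10 Hz means, 1000-event trains) but
deliberately idealizes the biology: release is deterministic (no vesicle
failures), glutamate is a clean square pulse, AMPA-receptor conductance is
reduced to a double-exponential drive for spike timing only, and the
neuron has no dendritic geometry — the distance map is qualitative, not a
morphological simulation. Passing tests therefore validate the model's
dynamics under idealized drive, not quantal variability or dendritic
filtering of real synapses.

# Numerical integration

The production integrator is a compiled fixed-step RK4 at `dt` = 0.005 ms.
The stiffest always-on rate is CBP binding (~200 ms⁻¹), comfortably inside
the RK4 stability region at that step; but two rates grow with calcium —
the cooperative calmodulin term (∝ ca²) and RyR activation (∝ ca⁴) — so the
integrator computes a local spectral-radius bound each step and subdivides
the step when large transients demand it. Free calcium is floored at
10⁻⁶ µM with a warning rather than allowed negative. Halving `dt` changes
the single-event peak by far less than 1% (asserted in the tests).

An adaptive stiff-capable path (`method = "lsoda"`, via deSolve, driving an
R-language right-hand side shared with nothing in the C++ code) exists for
cross-checking; the two integrators agree to ~10⁻⁵ relative on stimulated
transients. It is not the default because the R-level right-hand side is
orders of magnitude slower, which matters for the surrogate training
protocol.

The integrator also carries two bookkeeping states (cumulative
transmembrane flux and cumulative ER-sequestered calcium) whose defining
identities hold algebraically in the right-hand side; total-calcium balance
is therefore preserved to rounding error and asserted to 10⁻⁹ relative in
the tests.

# The input-output surrogate

The surrogate is a multi-input single-output Volterra functional series:
a constant, two single-input series up to third order with triangular
(symmetric-unique) self-kernels, a second-order cross-kernel and both
third-order cross-kernels (two lags from one input, one from the other).
Kernels are expanded on discrete orthonormal Laguerre bases — one decay
parameter per input, L₁ = L₂ = 3 functions (84 coefficients in total), a
5 s memory window at 1 ms sampling (5000 taps), with the filter implemented
by the exact Laguerre recursion. L is not dictated by anything in the
problem; 3 keeps the third-order term count tractable and is configurable.

Inputs are the spine membrane potential and the total NMDAr conductance;
the output is spine calcium. Mechanistic traces are downsampled to the
1 ms grid by bin averaging. Inputs are z-scored on pooled training
statistics (stored in the model) to condition the regression. Training
concatenates three conditions (pre only, post only, both) × two rates
(2, 10 Hz), drops the first memory window of every segment, and solves for
all coefficients at once by pseudoinverse (SVD) least squares. The two
decays are chosen by a coarse grid followed by projected gradient descent
with central numerical gradients (step 10⁻³ on the decay, stop on < 10⁻⁴
absolute improvement or 200 iterations, clipped inside (0,1)); starting
value 0.98. Accuracy is quoted as range-normalized RMS
(`normalized_rms()`): RMS error over the reference's max-minus-min, in
percent.

The package's default experiment (`run_io_protocol()`) and the test suite
run a reduced protocol — 100 events per train instead of 1000, three
seeds — which finishes in minutes; the full 1000-event protocol is a
single argument change. At the reduced scale the surrogate reproduces the
mechanistic model extremely closely at 2 Hz and degrades at 10 Hz, where
stacked coincidences push the system outside the polynomial's comfortable
range; training ≤ 2 Hz validation ≤ 10 Hz validation holds throughout.

# The linear baseline

The comparison model is the classic first-order calcium filter,
$d[\mathrm{Ca}]/dt = s_{lin}\,(-I_{NMDA}) - [\mathrm{Ca}]/\tau$, with
$\tau = 20$ ms and the *same* kinetic NMDAr current as drive. The
literature this model descends from leaves the current-to-concentration
scaling open; taking the raw $-I/(2FV)$ conversion (no buffering) makes
the linear model overshoot the mechanistic response by two orders of
magnitude, so the package calibrates $s_{lin}$ once against the
single-event no-AP amplitude (0.9 µM), the only choice consistent with a
baseline meant to "capture the first-order response". A consequence,
measured by the acceptance tests: because the magnesium-unblock
nonlinearity lives in $I_{NMDA}$ itself, the calibrated linear baseline
tracks this realization of the mechanistic model to within a few percent
NRMS — the residual nonlinearity (buffer saturation, VDCC influx)
contributes little RMS relative to the range set by the rare large
coincidence peaks. Reports of much larger linear-model errors depend on a
scaling convention this package found no self-consistent reconstruction
of; the discrepancy is documented rather than tuned away.

# Parameter discrepancies and open choices, summarized

* PMCA half-max 1 µM (alternative printed value 0.1 µM available).
* NCX conductance 0.0117 pS (alternative 0.117 pS available).
* Calmodulin forward rate read as 1×10⁸ mM⁻³ms⁻¹.
* Calbindin total 45 µM (unstated in the sources; standard spine value).
* Diffusion D, interface distance d: plausible defaults, configurable.
* NMDA calcium scalar and bAP waveform: the model's two calibrations
  (0.9 µM no-AP peak; ~700 nM / ~37 ms bAP transient).
* Linear-baseline scaling: calibrated to the single-event amplitude.
* Single-event NMDAr amplitude target 0.9 µM adopted over the alternative
  1.2 µM summary figure.

# Known limitations

* Deterministic ODEs: no stochastic single-channel behavior, no quantal
  release variability.
* The spine is voltage-clamped to rest + bAP superposition; subthreshold
  EPSP depolarization of the spine is neglected.
* The distance-attenuation map is qualitative; there is no compartmental
  morphology.
* The equilibrium buffered fraction implied by the printed buffer constants
  (~99.8%) exceeds the experimentally quoted ~95%.
* The surrogate is limited to third order; strongly superlinear 10 Hz
  responses are visibly harder for it.
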