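# spinecal

Calcium dynamics at a CA1 glutamatergic dendritic spine, implemented twice:

* a **mechanistic model** — a two-compartment (postsynaptic density + spine
  head) ODE system coupling an 8-state NMDA receptor scheme with
  voltage-dependent Mg²⁺ block, T-type voltage-dependent calcium channels
  driven by backpropagating action potentials (bAPs), PMCA/NCX Hill-type
  extrusion, calmodulin/calbindin/CBP buffering, and a SERCA + ryanodine
  receptor ER store; and
* an **input-output surrogate** — a two-input, third-order Volterra series
  on orthonormal Laguerre bases (with cross-kernels) that maps the spine's
  membrane potential and total NMDAr conductance directly to spine calcium,
  trained on the mechanistic model by pseudoinverse least squares with
  gradient-descent optimization of the basis decays.

The package is for computational neuroscientists who need spine calcium with
its real nonlinearities — magnesium unblock, buffer saturation,
spike-timing-dependent amplification — either in full mechanistic detail or
as a cheap surrogate suitable for many-synapse simulations.

## The core model in brief

PSD and spine head exchange calcium diffusively; NMDAr calcium current
enters the PSD as

$$I_{NMDA} = f_{Ca}\,s\,g_{max}(V)\,O(t)\,n_{NMDA}\,V_{Ca},\qquad
V_{Ca} = -\tfrac{RT}{2F}\log_{10}\!\big([\mathrm{Ca}]_o/[\mathrm{Ca}]_{spine}\big),$$

with $O(t)$ the open probability of the kinetic scheme and $g_{max}(V)$ the
Mg-blocked conductance. T-type current $g\,m^2h\,f_{drive}$ enters the head
during bAPs; PMCA and NCX extrude with Hill kinetics
($I = I_{MAX}\,[\mathrm{Ca}]^{h}/(K^h + [\mathrm{Ca}]^h)$, NCX's $I_{MAX}$
set by the 3Na⁺:1Ca²⁺ gradient potential); mass-action buffers and the ER
store shape the free-calcium response. A solved-for leak makes 50 nM an
exact resting fixed point. The surrogate is the standard MISO
Laguerre–Volterra expansion (order 3, $L_1 = L_2 = 3$, 5 s memory at 1 ms
sampling), with accuracy quoted as range-normalized RMS (NRMS, % of the
reference trace's max−min).

## Worked example

```r
library(spinecal)
cfg <- spine_config()          # the calibrated CA1 mushroom-spine model

# a presynaptic glutamate event with the postsynaptic neuron silent
peak_amplitude(single_pre_event(cfg, t_max = 1000))
#> [1] 0.8998198

# the same event with an elicited postsynaptic action potential
peak_amplitude(single_pre_with_ap(cfg, t_max = 1000))
#> [1] 9.326652

# a lone backpropagating AP (~150 um from the soma), peak in uM
rec <- single_bap_event(cfg)
c(peak = peak_amplitude(rec), tau_ms = decay_time(rec, method = "fit"))
#>       peak     tau_ms
#>  0.7105556 36.7803555
```

The numbers are the model's operating points: a subthreshold synaptic event
raises spine calcium to ~0.9 µM; pairing it with a postsynaptic spike
relieves the magnesium block while receptors are open and multiplies the
response tenfold; a bAP alone gives a ~0.7 µM, tens-of-ms transient carried
by T-type channels. Sweeping the pre→post interval maps the spike-timing
window:

```r
sw <- interval_sweep(cfg, intervals = seq(-30, 30, by = 1))
sw$interval[which.max(sw$peak)]   # strongest pairing: post 2 ms after pre
#> [1] 2
max(sw$peak)
#> [1] 9.403081
plot_interval_sweep(sw)
```

Training and validating the surrogate (here the reduced 100-event
protocol; the full protocol uses `n_events = 1000`):

```r
rep <- run_io_protocol(cfg, n_events = 100, n_events_val = 100, seed = 1)
rep$metrics        # training NRMS, per-rate validation NRMS, linear baseline
autoplot(rep)      # mechanistic vs surrogate vs linear traces
tidy(rep$model)    # one row per kernel coefficient
```

`autoplot()` methods exist for simulation records, fitted models and
surrogate reports; `write_spine_config()` / `write_volterra_model()` give
plain-text round-trippable serializations; `inst/cli/spinecal.R` wraps the
same functions for shell use.

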