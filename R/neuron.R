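#' Presynaptic / postsynaptic event trains
#'
#' `event_train()` wraps an ordered vector of event times into the tibble
#' format used throughout the package; `poisson_train()` draws a homogeneous
#' Poisson train (exponential inter-event intervals) reproducibly from a
#' seed, leaving the caller's RNG state untouched.
#'
#' @param times Event times (ms), non-negative and strictly increasing.
#' @param kind `"pre"` (presynaptic glutamate release) or `"post"`
#'   (postsynaptic spike / backpropagating action potential).
#' @return A tibble with columns `time` (ms) and `kind`, class `event_train`;
#'   generated trains carry `rate` and `seed` attributes.
#' @export
event_train <- function(times = numeric(), kind = c("pre", "post")) {
  kind <- match.arg(kind)
  if (length(times)) {
    if (any(!is.finite(times)) || any(times < 0)) {
      abort("event times must be finite and non-negative (ms)")
    }
    if (is.unsorted(times, strictly = TRUE)) {
      abort("event times must be strictly increasing")
    }
  }
  structure(tibble(time = as.numeric(times), kind = kind),
            class = c("event_train", class(tibble())))
}

#' @rdname event_train
#' @param rate Mean event rate (Hz), positive.
#' @param n_events Number of events to draw.
#' @param seed Integer seed; the same seed always gives the same train.
#' @param t_start Time of reference before the first interval (ms).
#' @export
poisson_train <- function(rate, n_events, seed, kind = c("pre", "post"),
                          t_start = 0) {
  kind <- match.arg(kind)
  if (!is.finite(rate) || rate <= 0) abort("`rate` must be positive (Hz)")
  if (n_events < 1) abort("`n_events` must be at least 1")
  isi <- with_seed(seed, rexp(n_events, rate = rate / 1000))
  out <- event_train(t_start + cumsum(isi), kind)
  attr(out, "rate") <- rate
  attr(out, "seed") <- seed
  out
}

# run code with a fixed seed, restoring the caller's RNG state afterwards
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

#' Izhikevich point-neuron parameters
#'
#' Standard two-variable quadratic integrate-and-fire parameters (the
#' regular-spiking set by default) plus the synaptic drive shape used to
#' elicit spikes: each presynaptic event injects a difference-of-exponentials
#' current of weight `syn_gain`.
#'
#' @param a,b,c,d Recovery and reset parameters of the model.
#' @param v_peak Spike cutoff (mV).
#' @param syn_gain Injected-current weight per presynaptic event (model
#'   current units).
#' @param syn_tau_rise,syn_tau_decay Synaptic current time constants (ms).
#' @return A list of class `izhikevich_params`.
#' @export
izhikevich_params <- function(a = 0.02, b = 0.2, c = -65, d = 8, v_peak = 30,
                              syn_gain = 30, syn_tau_rise = 0.5,
                              syn_tau_decay = 3) {
  structure(list(a = a, b = b, c = c, d = d, v_peak = v_peak,
                 syn_gain = syn_gain, syn_tau_rise = syn_tau_rise,
                 syn_tau_decay = syn_tau_decay),
            class = "izhikevich_params")
}

#' One Euler step of the Izhikevich neuron
#'
#' `v' = 0.04 v^2 + 5 v + 140 - u + I`, `u' = a (b v - u)`, with reset
#' `v <- c`, `u <- u + d` when `v` crosses `v_peak`.
#'
#' @param v Membrane potential (mV).
#' @param u Recovery variable.
#' @param i_syn Injected current.
#' @param p An [izhikevich_params()].
#' @param dt Time step (ms), positive.
#' @return List with `v`, `u` and logical `spiked` (TRUE exactly on reset).
#' @export
izhikevich_step <- function(v, u, i_syn, p = izhikevich_params(), dt = 0.1) {
  if (dt <= 0) abort("`dt` must be positive")
  v1 <- v + dt * (0.04 * v^2 + 5 * v + 140 - u + i_syn)
  u1 <- u + dt * p$a * (p$b * v - u)
  if (v1 >= p$v_peak) list(v = p$c, u = u1 + p$d, spiked = TRUE)
  else list(v = v1, u = u1, spiked = FALSE)
}

#' Simulate the Izhikevich neuron under synaptic drive
#'
#' Integrates the point neuron while presynaptic events inject
#' difference-of-exponentials currents, returning the voltage trace and the
#' spike times. Used to elicit postsynaptic action potentials from synaptic
#' stimulation; the spikes then reach the spine as parametric
#' backpropagating-AP waveforms.
#'
#' @param pre An `event_train` of presynaptic events (or numeric times, ms).
#' @param t_max Simulation horizon (ms).
#' @param p An [izhikevich_params()].
#' @param dt Integration step (ms).
#' @param i_extra Optional function of time (ms) giving extra injected
#'   current.
#' @return List with `trace` (tibble: `time`, `v`) and `spikes` (numeric, ms).
#' @export
izhikevich_run <- function(pre, t_max, p = izhikevich_params(), dt = 0.1,
                           i_extra = NULL) {
  pre_t <- if (is.data.frame(pre)) pre$time else as.numeric(pre)
  n <- ceiling(t_max / dt) + 1
  tt <- (seq_len(n) - 1) * dt
  i_syn <- numeric(n)
  for (tp in pre_t) {
    idx <- which(tt >= tp & tt <= tp + 12 * p$syn_tau_decay)
    dtp <- tt[idx] - tp
    i_syn[idx] <- i_syn[idx] + p$syn_gain *
      (exp(-dtp / p$syn_tau_decay) - exp(-dtp / p$syn_tau_rise))
  }
  if (!is.null(i_extra)) i_syn <- i_syn + i_extra(tt)
  v <- numeric(n)
  v[1] <- p$c
  u <- p$b * p$c
  spikes <- numeric()
  for (i in seq_len(n - 1)) {
    st <- izhikevich_step(v[i], u, i_syn[i], p, dt)
    v[i + 1] <- st$v
    u <- st$u
    if (st$spiked) spikes <- c(spikes, tt[i + 1])
  }
  list(trace = tibble(time = tt, v = v), spikes = spikes)
}

#' Backpropagating action potential waveform
#'
#' Parametric spine-voltage transient of a backpropagating somatic spike: a
#' peak-normalized difference of exponentials scaled by the somatic spike
#' amplitude and a distance-dependent attenuation factor (about 30%
#' attenuation, i.e. factor ~0.7, at the ~150 um synapses the model is
#' calibrated for).
#'
#' @param amp Somatic spike amplitude above rest (mV).
#' @param tau_rise,tau_decay Rise and decay time constants (ms),
#'   `tau_decay > tau_rise`.
#' @param atten Attenuation factor at the spine, in (0, 1].
#' @param v_rest Resting potential (mV).
#' @return A list of class `bap_waveform`.
#' @export
bap_waveform <- function(amp = 75, tau_rise = 0.6, tau_decay = 8,
                         atten = 0.7, v_rest = -65) {
  if (atten <= 0 || atten > 1) abort("`atten` must lie in (0, 1]")
  if (tau_decay <= tau_rise) abort("need `tau_decay` > `tau_rise`")
  structure(list(amp = amp, tau_rise = tau_rise, tau_decay = tau_decay,
                 atten = atten, v_rest = v_rest),
            class = "bap_waveform")
}

# peak value of exp(-t/td) - exp(-t/tr), for peak normalization
.bap_norm <- function(tr, td) {
  tpk <- log(td / tr) * tr * td / (td - tr)
  exp(-tpk / td) - exp(-tpk / tr)
}

#' Spine voltage contributed by a backpropagating action potential
#'
#' @param t_since_spike Time since the somatic spike (ms), >= 0. Vectorized.
#' @param w A [bap_waveform()].
#' @return Spine membrane potential (mV); tends to `w$v_rest` for large times.
#' @export
bap_voltage <- function(t_since_spike, w = bap_waveform()) {
  if (any(t_since_spike < 0)) abort("`t_since_spike` must be >= 0")
  shape <- (exp(-t_since_spike / w$tau_decay) -
              exp(-t_since_spike / w$tau_rise)) /
    .bap_norm(w$tau_rise, w$tau_decay)
  w$v_rest + w$amp * w$atten * shape
}

#' Spine voltage trace from a postsynaptic spike train
#'
#' Superposition of the resting potential and one bAP waveform per
#' postsynaptic spike.
#'
#' @param t Times at which to evaluate (ms). Vectorized.
#' @param post_times Postsynaptic spike times (ms).
#' @param w A [bap_waveform()].
#' @return Spine membrane potential (mV).
#' @export
spine_voltage <- function(t, post_times, w = bap_waveform()) {
  v <- rep(w$v_rest, length(t))
  for (ts in post_times) {
    idx <- which(t >= ts)
    v[idx] <- v[idx] + bap_voltage(t[idx] - ts, w) - w$v_rest
  }
  v
}

#' Backpropagation attenuation as a function of distance from the soma
#'
#' Logistic distance-to-attenuation map standing in for a full compartmental
#' morphology: ~0.7 at the 150 um calibration distance, falling to near zero
#' beyond ~300 um where backpropagation becomes negligible. Intended for
#' qualitative distance studies only.
#'
#' @param distance Distance from the soma (um). Vectorized.
#' @return Attenuation factor in (0, 1).
#' @export
bap_attenuation <- function(distance) {
  if (any(distance < 0)) abort("`distance` must be non-negative (um)")
  1 / (1 + exp((distance - 183.5) / 39.6))
}
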