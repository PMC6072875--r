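#' Single-event validation protocols
#'
#' The three single-event protocols used to calibrate and validate the
#' mechanistic model: a presynaptic glutamate event with the postsynaptic
#' neuron silent; the same event with a postsynaptic action potential
#' elicited through the point neuron (its backpropagating waveform reaching
#' the spine); and a lone backpropagating action potential.
#'
#' @param config A [spine_config()].
#' @param t_max Simulation horizon (ms).
#' @param t_event Event time (ms).
#' @return A `spine_sim` tibble; for `single_pre_with_ap()` the elicited
#'   spike times are attached as attribute `spikes`.
#' @name single_event_protocols
NULL

#' @rdname single_event_protocols
#' @export
single_pre_event <- function(config = spine_config(), t_event = 100,
                             t_max = 1100) {
  run_simulation(config, pre = t_event, post = NULL, t_max = t_max)
}

#' @rdname single_event_protocols
#' @export
single_pre_with_ap <- function(config = spine_config(), t_event = 100,
                               t_max = 1100) {
  neuron <- izhikevich_run(t_event, t_max = t_event + 50, p = config$izh)
  if (!length(neuron$spikes)) {
    abort("synaptic drive failed to elicit a postsynaptic spike; increase `izh$syn_gain`")
  }
  rec <- run_simulation(config, pre = t_event, post = neuron$spikes,
                        t_max = t_max)
  attr(rec, "spikes") <- neuron$spikes
  rec
}

#' @rdname single_event_protocols
#' @export
single_bap_event <- function(config = spine_config(), t_event = 100,
                             t_max = 600) {
  run_simulation(config, pre = NULL, post = t_event, t_max = t_max)
}

#' Sweep the pre/post interval and measure peak calcium
#'
#' Runs [pre_post_protocol()] at each signed interval and records the peak
#' spine calcium, reproducing the spike-timing sweep: calcium amplification
#' is largest when the backpropagating action potential follows the
#' glutamate event by a few milliseconds (magnesium unblock while NMDA
#' receptors are still open), decays back to the presynaptic-only level
#' within ~80 ms, and is much weaker for post-before-pre orderings.
#'
#' @param config A [spine_config()].
#' @param intervals Signed intervals (ms); default covers -100..100 ms with
#'   1 ms spacing.
#' @param t_tail Recording time after the later event (ms).
#' @return A tibble with columns `interval` (ms) and `peak` (uM).
#' @export
interval_sweep <- function(config = spine_config(),
                           intervals = seq(-100, 100, by = 1),
                           t_tail = 400) {
  if (any(!is.finite(intervals))) abort("`intervals` must be finite")
  peaks <- purrr::map_dbl(intervals, function(iv) {
    peak_amplitude(pre_post_protocol(config, iv, t_tail = t_tail))
  })
  tibble(interval = intervals, peak = peaks)
}

#' Linear first-order calcium baseline
#'
#' The classic linear calcium model: free calcium driven by the NMDA
#' receptor calcium current and relaxing with a single time constant,
#' `d[Ca]/dt = s * (-I_NMDA(t)) - ([Ca] - ca_rest)/tau`. The same kinetic
#' NMDAr current as the mechanistic model is used as the drive, so any
#' difference from the mechanistic response reflects the nonlinearities the
#' linear model cannot express (magnesium-unblock amplification, buffer
#' saturation, voltage-dependent influx).
#'
#' @param tau_ca Decay time constant (ms).
#' @param influx_scale Dimensionless scaling from the current-derived
#'   concentration rate to the linear model's effective influx; calibrated
#'   once so the linear model's single-event (no-AP) response matches the
#'   mechanistic first-order response amplitude.
#' @param ca_rest Resting calcium (uM).
#' @return A list of class `linear_ca_params`.
#' @export
linear_ca_params <- function(tau_ca = 20, influx_scale = 0.00706,
                             ca_rest = 0.05) {
  if (tau_ca <= 0) abort("`tau_ca` must be positive (ms)")
  structure(list(tau_ca = tau_ca, influx_scale = influx_scale,
                 ca_rest = ca_rest), class = "linear_ca_params")
}

#' @rdname linear_ca_params
#' @param i_nmda NMDAr calcium current trace (pA, inward-negative),
#'   uniformly sampled.
#' @param dt Sampling interval of `i_nmda` (ms).
#' @param p A [linear_ca_params()].
#' @param config A [spine_config()] (for volume and constants).
#' @return `linear_model_trace()`: calcium trace (uM), same length as
#'   `i_nmda`, integrated exactly per sampling interval (exponential
#'   update).
#' @export
linear_model_trace <- function(i_nmda, dt, p = linear_ca_params(),
                               config = spine_config()) {
  drive <- p$influx_scale *
    current_to_rate(-i_nmda, config$geometry$v_spine, config$constants)
  n <- length(i_nmda)
  ca <- numeric(n)
  ca[1] <- p$ca_rest
  decay <- exp(-dt / p$tau_ca)
  gain <- p$tau_ca * (1 - decay)
  for (i in seq_len(n - 1)) {
    # exact step for piecewise-constant drive
    ca[i + 1] <- p$ca_rest + (ca[i] - p$ca_rest) * decay + drive[i] * gain
  }
  ca
}

#' Build the surrogate training set from the mechanistic model
#'
#' Simulates the mechanistic model under the surrogate training protocol:
#' the three stimulation conditions (presynaptic only, postsynaptic only,
#' both) each driven by Poisson event trains at a low and a high mean rate
#' (2 and 10 Hz by default). Traces are recorded as 1 ms bin averages of
#' postsynaptic potential, total NMDAr conductance and spine calcium — the
#' two surrogate inputs and its output.
#'
#' @param config A [spine_config()].
#' @param n_events Events per train (1000 in the full protocol; reduced
#'   values give proportionally shorter training sets).
#' @param rates Mean Poisson rates (Hz).
#' @param seed Integer seed; sub-seeds for each train are derived from it.
#' @param conditions Subset of `c("pre", "post", "both")`.
#' @param dt_io Surrogate sampling interval (ms).
#' @return A tibble with columns `segment`, `condition`, `rate`, `time`,
#'   `v`, `g`, `ca`.
#' @export
make_io_training_set <- function(config = spine_config(), n_events = 1000,
                                 rates = c(2, 10), seed = 1,
                                 conditions = c("pre", "post", "both"),
                                 dt_io = 1) {
  out <- list()
  seg <- 0
  for (rate in rates) {
    for (cond in conditions) {
      seg <- seg + 1
      pre <- if (cond %in% c("pre", "both")) {
        poisson_train(rate, n_events, seed = seed + 13 * seg, kind = "pre")
      }
      post <- if (cond %in% c("post", "both")) {
        poisson_train(rate, n_events, seed = seed + 13 * seg + 7,
                      kind = "post")
      }
      t_max <- max(.event_times(pre), .event_times(post), 0) + 500
      rec <- run_simulation(config, pre, post, t_max = t_max,
                            record_dt = dt_io, average = TRUE)
      out[[seg]] <- tibble(segment = seg, condition = cond, rate = rate,
                           time = rec$time, v = rec$v, g = rec$g_nmda,
                           ca = rec$ca_spine)
    }
  }
  dplyr::bind_rows(out)
}

#' Train and validate the input-output surrogate
#'
#' Runs the full surrogate workflow: build the training set from the
#' mechanistic model, optionally optimize the Laguerre decays, fit the
#' third-order two-input Volterra model, then validate against fresh
#' ("naive") Poisson trains at each rate with both stimulation pathways
#' active. Reports range-normalized RMS errors (percent) for training and
#' each validation rate, and the linear-baseline errors on the same naive
#' trains for comparison.
#'
#' @param config A [spine_config()].
#' @param n_events Events per training train.
#' @param n_events_val Events per validation train.
#' @param seed Integer seed (training and validation trains use disjoint
#'   derived seeds).
#' @param rates Mean Poisson rates (Hz).
#' @param n_basis Laguerre functions per input.
#' @param memory Memory window in taps (at `dt_io` sampling).
#' @param dt_io Surrogate sampling interval (ms).
#' @param optimize If `TRUE`, optimize the decays by grid-seeded gradient
#'   descent before the final fit.
#' @param decays Initial decays `c(alpha_v, alpha_g)`.
#' @param grid,max_iter Decay-search controls (see [optimize_decay()]).
#' @param linear_baseline Also evaluate the linear first-order model on the
#'   validation trains.
#' @return A list of class `io_report`: the fitted `model`, a `metrics`
#'   tibble (one row per quantity: training NRMS, per-rate validation NRMS,
#'   per-rate linear NRMS) and the validation traces.
#' @export
run_io_protocol <- function(config = spine_config(), n_events = 1000,
                            n_events_val = 200, seed = 1, rates = c(2, 10),
                            n_basis = c(3, 3), memory = 5000, dt_io = 1,
                            optimize = TRUE, decays = c(0.98, 0.98),
                            grid = c(0.95, 0.98, 0.995), max_iter = 200,
                            linear_baseline = TRUE) {
  train <- make_io_training_set(config, n_events, rates, seed = seed,
                                dt_io = dt_io)
  if (optimize) {
    opt <- optimize_decay(train, init = decays, n_basis = n_basis,
                          memory = memory, dt = dt_io, grid = grid,
                          max_iter = max_iter)
    model <- opt$model
  } else {
    model <- volterra_fit(train,
                          laguerre_basis(decays[1], n_basis[1], memory,
                                         dt_io),
                          laguerre_basis(decays[2], n_basis[2], memory,
                                         dt_io))
    opt <- NULL
  }
  metrics <- list(tibble(quantity = "train_nrms", rate = NA_real_,
                         value = model$train_nrms))
  traces <- list()
  for (rate in rates) {
    pre <- poisson_train(rate, n_events_val, seed = seed + 1000 + rate,
                         kind = "pre")
    post <- poisson_train(rate, n_events_val, seed = seed + 2000 + rate,
                          kind = "post")
    t_max <- max(pre$time, post$time) + 500
    rec <- run_simulation(config, pre, post, t_max = t_max,
                          record_dt = dt_io, average = TRUE)
    keep <- seq_len(nrow(rec)) > memory
    if (!any(keep)) abort("validation train shorter than the memory window")
    pred <- predict(model, rec$v, rec$g_nmda)
    nrms_io <- normalized_rms(pred[keep], rec$ca_spine[keep])
    metrics <- c(metrics, list(tibble(quantity = "validation_nrms",
                                      rate = rate, value = nrms_io)))
    tr <- tibble(rate = rate, time = rec$time, ca_mech = rec$ca_spine,
                 ca_io = pred)
    if (linear_baseline) {
      lin <- linear_model_trace(rec$i_nmda, dt_io, config = config)
      metrics <- c(metrics, list(tibble(
        quantity = "linear_nrms", rate = rate,
        value = normalized_rms(lin[keep], rec$ca_spine[keep]))))
      tr$ca_linear <- lin
    }
    traces[[as.character(rate)]] <- tr
  }
  structure(list(model = model, metrics = dplyr::bind_rows(metrics),
                 traces = dplyr::bind_rows(traces), seed = seed,
                 n_events = n_events, n_events_val = n_events_val,
                 decay_search = opt$trace),
            class = "io_report")
}

#' @export
print.io_report <- function(x, ...) {
  cat("<io_report> Volterra surrogate of the mechanistic spine model\n")
  cat("  training events:", x$n_events, "per train; validation:",
      x$n_events_val, "per train; seed", x$seed, "\n")
  m <- x$metrics
  for (i in seq_len(nrow(m))) {
    cat(sprintf("  %-16s %s %6.2f %%\n", m$quantity[i],
                ifelse(is.na(m$rate[i]), "      ",
                       sprintf("%2g Hz ", m$rate[i])), m$value[i]))
  }
  invisible(x)
}

#' Compare the linear baseline against the mechanistic model
#'
#' Drives the mechanistic model with joint pre+post Poisson trains at a
#' given rate, feeds the recorded NMDAr current to the linear first-order
#' model, and reports the range-normalized RMS difference between the two
#' calcium traces, averaged over seeds.
#'
#' @param config A [spine_config()].
#' @param rate Mean Poisson rate (Hz).
#' @param n_events Events per train.
#' @param seeds Integer seeds to average over.
#' @param p A [linear_ca_params()].
#' @param dt_io Sampling interval (ms).
#' @return A tibble with one row per seed and columns `rate`, `seed`,
#'   `nrms`.
#' @export
linear_baseline_nrms <- function(config = spine_config(), rate = 2,
                                 n_events = 100, seeds = 1:3,
                                 p = linear_ca_params(), dt_io = 1) {
  purrr::map_dfr(seeds, function(s) {
    pre <- poisson_train(rate, n_events, seed = s * 101 + rate, kind = "pre")
    post <- poisson_train(rate, n_events, seed = s * 101 + rate + 57,
                          kind = "post")
    rec <- run_simulation(config, pre, post,
                          t_max = max(pre$time, post$time) + 500,
                          record_dt = dt_io, average = TRUE)
    lin <- linear_model_trace(rec$i_nmda, dt_io, p, config)
    tibble(rate = rate, seed = s,
           nrms = normalized_rms(lin, rec$ca_spine))
  })
}
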