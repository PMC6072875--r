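#' Assemble a full spine-model configuration
#'
#' Collects every component parameter block — geometry, ion environment,
#' NMDA receptor scheme and conductance parameters, T-type channel, pumps,
#' buffers, ER store, backpropagating-AP waveform, glutamate pulse shape,
#' point-neuron parameters — together with solver settings and initial
#' conditions, into one validated configuration object. All defaults
#' reproduce the calibrated CA1 mushroom-spine model.
#'
#' @param constants A [spine_constants()].
#' @param geometry A [spine_geometry()].
#' @param env An [ion_environment()].
#' @param nmdar An [nmdar_params()].
#' @param nmdar_scheme An [nmdar_scheme()].
#' @param vdcc A [ttype_params()].
#' @param pmca,ncx [pump_params()] for the two extrusion routes.
#' @param cam,cbp,calbindin Buffer parameter blocks (see [buffer_params]).
#' @param er An [er_store_params()].
#' @param bap A [bap_waveform()].
#' @param izh An [izhikevich_params()].
#' @param glu_amp Glutamate pulse amplitude per presynaptic event (mM).
#' @param glu_duration Glutamate pulse duration (ms).
#' @param method Integrator: `"rk4"` (compiled fixed-step, default) or
#'   `"lsoda"` (adaptive, via deSolve, much slower; useful as a
#'   cross-check).
#' @param dt Fixed integration step (ms).
#' @param record_dt Recording interval (ms), must be >= `dt`.
#' @param init_ca Initial free calcium in both compartments (uM).
#'
#' @return A list of class `spine_config`.
#' @export
spine_config <- function(constants = spine_constants(),
                         geometry = spine_geometry(),
                         env = ion_environment(),
                         nmdar = nmdar_params(),
                         nmdar_scheme = spinecal::nmdar_scheme(),
                         vdcc = ttype_params(),
                         pmca = pump_params("pmca"),
                         ncx = pump_params("ncx"),
                         cam = cam_params(),
                         cbp = cbp_params(),
                         calbindin = calbindin_params(),
                         er = er_store_params(),
                         bap = bap_waveform(),
                         izh = izhikevich_params(),
                         glu_amp = 1, glu_duration = 1,
                         method = c("rk4", "lsoda"),
                         dt = 0.005, record_dt = 0.1,
                         init_ca = 0.05) {
  method <- match.arg(method)
  if (record_dt < dt) abort("`record_dt` must be >= `dt`")
  if (init_ca <= 0) abort("`init_ca` must be positive (uM)")
  structure(
    list(constants = constants, geometry = geometry, env = env,
         nmdar = nmdar, scheme = nmdar_scheme, vdcc = vdcc, pmca = pmca,
         ncx = ncx, cam = cam, cbp = cbp, calbindin = calbindin, er = er,
         bap = bap, izh = izh,
         glu = list(amp = glu_amp, duration = glu_duration),
         solver = list(method = method, dt = dt, record_dt = record_dt),
         init = list(ca = init_ca)),
    class = "spine_config")
}

#' @export
print.spine_config <- function(x, ...) {
  cat("<spine_config>\n")
  cat("  geometry: V_spine", x$geometry$v_spine, "um^3, V_PSD",
      x$geometry$v_psd, "um^3\n")
  cat("  NMDAr:", x$nmdar$n_receptors, "receptors,",
      length(x$scheme$states), "states; f_ca", x$nmdar$f_ca,
      "x scale", x$nmdar$ca_scale, "\n")
  cat("  VDCC: ", x$vdcc$n_open, "x", x$vdcc$g_single, "pS (T-type)\n")
  cat("  ER store:", if (x$er$enabled) "enabled" else "disabled", "\n")
  cat("  solver:", x$solver$method, "dt", x$solver$dt, "ms, record",
      x$solver$record_dt, "ms\n")
  invisible(x)
}

# state-vector layout shared with the compiled integrator
.state_names <- function(config) {
  c("ca_psd", "ca_spine", paste0("n_", config$scheme$states), "m", "h",
    "cam_bound", "cbp_bound", paste0("cb_", rep(0:2, each = 3), rep(0:2, 3)),
    "serca_s2", "ryr_open", "cum_in", "cum_er")
}

#' Initial (resting) state vector for the assembled model
#'
#' Every kinetic state is placed at its equilibrium for the configured
#' resting calcium and resting potential, so that with no stimulation the
#' model sits at an exact fixed point (the leak term of
#' [resting_leak_rate()] closes the balance).
#'
#' @param config A [spine_config()].
#' @return Named numeric state vector.
#' @export
initial_state <- function(config = spine_config()) {
  ca0 <- config$init$ca
  occ <- numeric(length(config$scheme$states))
  occ[config$scheme$resting_state] <- 1
  g <- vdcc_gating(config$bap$v_rest, config$vdcc)
  bufs <- buffer_equilibrium(ca0, config)
  st <- store_equilibrium(ca0, config)
  y <- c(ca0, ca0, occ, g$m_inf, g$h_inf, bufs$cam_bound, bufs$cbp_bound,
         bufs$calbindin, st$serca_s2, st$ryr_open, 0, 0)
  names(y) <- .state_names(config)
  y
}

# parameter list handed to the compiled integrator
.cpp_pars <- function(config, leak) {
  e <- config$scheme$edges
  states <- config$scheme$states
  nm <- c(unclass(config$nmdar),
          list(from = match(e$from, states) - 1L,
               to = match(e$to, states) - 1L,
               glu = as.integer(e$glu_order > 0), rate = e$rate,
               open_idx = config$scheme$open_state - 1L))
  list(constants = unclass(config$constants),
       geometry = unclass(config$geometry),
       env = unclass(config$env), nmdar = nm,
       vdcc = unclass(config$vdcc), pmca = unclass(config$pmca),
       ncx = unclass(config$ncx), cam = unclass(config$cam),
       cbp = unclass(config$cbp), calbindin = unclass(config$calbindin),
       er = unclass(config$er), leak = leak, bap = unclass(config$bap),
       glu = config$glu)
}

.event_times <- function(x) {
  if (is.null(x)) numeric() else if (is.data.frame(x)) x$time
  else as.numeric(x)
}

#' Run the mechanistic spine calcium simulation
#'
#' Integrates the coupled system — PSD and spine calcium, NMDA receptor
#' occupancies, T-type gating, the three buffers, and the ER store — driven
#' by presynaptic glutamate events and postsynaptic backpropagating action
#' potentials, and records uniformly sampled traces.
#'
#' @param config A [spine_config()].
#' @param pre Presynaptic events: an [event_train()] or numeric times (ms).
#' @param post Postsynaptic spikes (bAP arrival times at the spine), same
#'   formats.
#' @param t_max Simulation horizon (ms).
#' @param record_dt Recording interval (ms); defaults to the configured one.
#' @param average If `TRUE`, recorded samples are means over each recording
#'   bin (the right choice when downsampling for the input-output model);
#'   if `FALSE` (default) they are instantaneous values at the bin edges.
#' @param state0 Optional initial state vector (as from [initial_state()],
#'   which is also the default); lets a simulation start away from rest.
#'
#' @return A tibble of class `spine_sim` with columns `time` (ms),
#'   `ca_spine`, `ca_psd` (uM), `v` (mV), `glu` (mM), `open` (NMDAr open
#'   probability), `g_nmda` (pS), per-component currents (pA) and buffer/ER
#'   fluxes (uM/ms), plus bookkeeping columns `cum_in`/`cum_er` (uM).
#'   Attributes: `config`, `final_state`, `floor_hits`, `leak`.
#' @examples
#' \donttest{
#' cfg <- spine_config()
#' rec <- run_simulation(cfg, pre = 20, post = NULL, t_max = 300)
#' max(rec$ca_spine)
#' }
#' @export
run_simulation <- function(config = spine_config(), pre = NULL, post = NULL,
                           t_max = 1000, record_dt = NULL, average = FALSE,
                           state0 = NULL) {
  pre_t <- .event_times(pre)
  post_t <- .event_times(post)
  if (is.unsorted(pre_t) || is.unsorted(post_t)) {
    abort("event times must be sorted increasingly")
  }
  record_dt <- record_dt %||% config$solver$record_dt
  leak <- resting_leak_rate(config)
  y0 <- state0 %||% initial_state(config)
  if (length(y0) != length(initial_state(config))) {
    abort("`state0` has the wrong length")
  }
  if (config$solver$method == "lsoda") {
    rec <- .run_lsoda(config, leak, y0, pre_t, post_t, t_max, record_dt)
    floor_hits <- 0
    final <- attr(rec, "final_state")
  } else {
    res <- .sim_spine_cpp(.cpp_pars(config, leak), unname(y0), pre_t, post_t,
                          t_max, config$solver$dt, record_dt, average)
    rec <- as_tibble(as.data.frame(res$record))
    floor_hits <- res$floor_hits
    final <- setNames(res$state, names(y0))
  }
  if (floor_hits > 0) {
    warn(sprintf("free calcium hit the 1e-6 uM floor %d times", floor_hits))
  }
  structure(rec, class = c("spine_sim", class(tibble())),
            config = config, final_state = final, floor_hits = floor_hits,
            leak = leak)
}

# R-level right-hand side, used by the adaptive integrator and as an
# independent cross-check of the compiled path in the tests
spine_rhs_r <- function(t, y, config, leak, pre_t, post_t) {
  ns <- length(config$scheme$states)
  ca_psd <- max(y[1], 1e-9)
  ca <- max(y[2], 1e-9)
  occ <- y[3:(2 + ns)]
  m <- y[3 + ns]; h <- y[4 + ns]
  bstate <- list(cam_bound = y[5 + ns], cbp_bound = y[6 + ns],
                 calbindin = y[(7 + ns):(15 + ns)])
  sstate <- list(serca_s2 = y[16 + ns], ryr_open = y[17 + ns])

  glu <- 0
  for (tp in pre_t) if (t >= tp && t - tp < config$glu$duration) {
    glu <- glu + config$glu$amp
  }
  v <- spine_voltage(t, post_t[post_t <= t], config$bap)

  docc <- nmdar_derivatives(pmin(pmax(occ, 0), 1), glu, config$scheme)
  g_nmda <- nmdar_conductance(min(max(occ[config$scheme$open_state], 0), 1),
                              v, config$env, config$nmdar, config$constants)
  i_nmda <- nmdar_calcium_current(g_nmda, nernst_ca_potential(
    ca, config$env, config$constants), config$nmdar$f_ca,
    config$nmdar$ca_scale)
  dmh <- vdcc_gating_derivatives(v, min(max(m, 0), 1), min(max(h, 0), 1),
                                 config$vdcc)
  i_vdcc <- vdcc_current(v, min(max(m, 0), 1), min(max(h, 0), 1), ca,
                         config$env, config$vdcc, config$constants)
  i_pmca <- pmca_current(ca, config$pmca)
  i_ncx <- ncx_current(ca, config$env, config$ncx, config$constants)
  bf <- buffer_fluxes(ca, bstate, config)
  se <- serca_flux(ca, sstate, config)
  ry <- ryr_flux(ca, sstate, config)

  diff <- psd_diffusion_rates(ca_psd, ca, config$geometry)
  c_psd <- function(i) current_to_rate(i, config$geometry$v_psd,
                                       config$constants)
  c_sp <- function(i) current_to_rate(i, config$geometry$v_spine,
                                      config$constants)
  d_ca_psd <- -c_psd(i_nmda) + diff$psd
  d_ca <- diff$spine - c_sp(i_vdcc + i_pmca + i_ncx) + leak + bf$j +
    se$j + ry$j
  d_cum_in <- -c_sp(i_nmda + i_vdcc + i_pmca + i_ncx) + leak
  d_cum_er <- -(se$j + ry$j)
  c(d_ca_psd, d_ca, docc, dmh, bf$d_cam, bf$d_cbp, bf$d_calbindin,
    se$d_s2, ry$d_open, d_cum_in, d_cum_er)
}

.run_lsoda <- function(config, leak, y0, pre_t, post_t, t_max, record_dt) {
  times <- seq(0, t_max, by = record_dt)
  # break integration at glutamate pulse edges so lsoda sees them
  edges <- sort(unique(c(pre_t, pre_t + config$glu$duration, post_t)))
  edges <- edges[edges > 0 & edges < t_max]
  sol <- deSolve::lsoda(
    y = unname(y0), times = sort(unique(c(times, edges))),
    func = function(t, y, parms) {
      list(spine_rhs_r(t, y, config, leak, pre_t, post_t))
    },
    parms = NULL, rtol = 1e-8, atol = 1e-10, hmax = 0.5)
  if (attr(sol, "istate")[1] < 0) abort("lsoda failed to converge")
  keep <- sol[, 1] %in% times
  tt <- sol[keep, 1]
  y <- sol[keep, -1, drop = FALSE]
  ns <- length(config$scheme$states)
  v <- spine_voltage(tt, post_t, config$bap)
  open <- y[, 2 + config$scheme$open_state]
  g_nmda <- nmdar_conductance(pmin(pmax(open, 0), 1), v, config$env,
                              config$nmdar, config$constants)
  rec <- tibble(
    time = tt, ca_spine = y[, 2], ca_psd = y[, 1], v = v,
    glu = vapply(tt, function(t) {
      sum(config$glu$amp * (t >= pre_t & t - pre_t < config$glu$duration))
    }, numeric(1)),
    open = open, g_nmda = g_nmda,
    i_nmda = nmdar_calcium_current(
      g_nmda, nernst_ca_potential(pmax(y[, 2], 1e-9), config$env,
                                  config$constants),
      config$nmdar$f_ca, config$nmdar$ca_scale),
    i_vdcc = NA_real_, i_pmca = pmca_current(pmax(y[, 2], 0), config$pmca),
    i_ncx = NA_real_, j_buf = NA_real_, j_er = NA_real_,
    m = y[, 3 + ns], cum_in = y[, 16 + ns + 2], cum_er = y[, 17 + ns + 2])
  attr(rec, "final_state") <- setNames(y[nrow(y), ], names(y0))
  rec
}

#' Single pre/post pairing protocol
#'
#' One presynaptic glutamate event and one backpropagating action potential
#' separated by a signed interval (positive: post follows pre), the protocol
#' behind the spike-timing interval sweep.
#'
#' @param config A [spine_config()].
#' @param interval Signed pre-to-post interval (ms); negative means the bAP
#'   precedes the glutamate event.
#' @param t_pre Time of the presynaptic event (ms).
#' @param t_tail Recording time after the later event (ms).
#' @inheritParams run_simulation
#' @return A `spine_sim` tibble (see [run_simulation()]).
#' @export
pre_post_protocol <- function(config = spine_config(), interval,
                              t_pre = 100, t_tail = 800, record_dt = NULL) {
  if (!is.finite(interval)) abort("`interval` must be finite (ms)")
  t_post <- t_pre + interval
  if (t_post < 0) abort("interval places the bAP before time 0")
  run_simulation(config, pre = t_pre, post = t_post,
                 t_max = max(t_pre, t_post) + t_tail, record_dt = record_dt)
}

#' Peak amplitude of a recorded variable
#'
#' Maximum of a recorded trace over a time window, optionally baseline
#' subtracted. Exact for the recorded samples (no interpolation).
#'
#' @param rec A `spine_sim` tibble (or any tibble with a `time` column).
#' @param variable Column to measure (default `"ca_spine"`).
#' @param window Optional `c(t0, t1)` (ms) restricting the search.
#' @param baseline `NULL` (no subtraction), a number, or `"first"` to
#'   subtract the first value in the window.
#' @return Peak value (same units as the variable).
#' @export
peak_amplitude <- function(rec, variable = "ca_spine", window = NULL,
                           baseline = NULL) {
  if (!variable %in% names(rec)) {
    abort(sprintf("variable '%s' was not recorded", variable))
  }
  x <- rec[[variable]]
  tt <- rec$time
  if (!is.null(window)) {
    keep <- tt >= window[1] & tt <= window[2]
    x <- x[keep]
  }
  if (!length(x)) abort("empty window")
  b <- 0
  if (identical(baseline, "first")) b <- x[1]
  else if (is.numeric(baseline)) b <- baseline
  max(x) - b
}

#' Decay time of a transient
#'
#' Single-number summary of how fast a transient decays. Calcium transients
#' in this model are not single exponentials (buffer re-equilibration makes
#' the early decay faster than the tail), so two conventions are offered:
#'
#' * `"efold"`: time from the peak until the trace first falls to `1/e` of
#'   the peak elevation above baseline.
#' * `"fit"`: time constant of a single exponential fitted (least squares on
#'   the log) from the peak through the first two e-folds of decay — the
#'   bulk of the visible transient, and the convention used when comparing
#'   against reported "decay ~X ms" figures.
#'
#' @param rec A `spine_sim` tibble.
#' @param variable Column to measure.
#' @param baseline Baseline value; defaults to the first recorded sample.
#' @param method `"efold"` or `"fit"` (see above).
#' @return Decay time (ms), or `NA` if the trace never falls far enough.
#' @export
decay_time <- function(rec, variable = "ca_spine", baseline = NULL,
                       method = c("efold", "fit")) {
  method <- match.arg(method)
  x <- rec[[variable]]
  b <- baseline %||% x[1]
  ipk <- which.max(x)
  pk <- x[ipk] - b
  target <- if (method == "efold") exp(-1) else exp(-2)
  after <- which(x[ipk:length(x)] - b <= pk * target)
  if (!length(after)) return(NA_real_)
  iend <- ipk + after[1] - 1
  if (method == "efold") return(rec$time[iend] - rec$time[ipk])
  seg <- ipk:iend
  fit <- stats::lm.fit(cbind(1, rec$time[seg]), log(x[seg] - b))
  -1 / fit$coefficients[2]
}
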