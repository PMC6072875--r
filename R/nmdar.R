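#' NMDA receptor kinetic scheme
#'
#' Loads the 8-state NMDA receptor kinetic scheme (resting, mono/di-liganded,
#' desensitized, pre-open and open states) from a plain-text edge list. Each
#' edge carries a rate constant (ms^-1) and a `glu_order` flag: edges with
#' `glu_order = 1` are glutamate-association steps whose rate scales linearly
#' with the glutamate concentration (rate constant then in mM^-1 ms^-1).
#'
#' The shipped table follows the published GluN1/GluN2A scheme of Erreger and
#' colleagues; supplying `file` swaps in any other scheme with the same
#' column layout (`from`, `to`, `rate`, `glu_order`), as long as exactly one
#' state is named `o` (open).
#'
#' @param file Path to a tab-separated edge list. Defaults to the table
#'   shipped with the package.
#'
#' @return An object of class `nmdar_scheme`: list with `states` (character),
#'   `edges` (tibble), `open_state` (index) and `resting_state` (index).
#' @export
nmdar_scheme <- function(file = system.file("extdata", "nmdar_rates.tsv",
                                            package = "spinecal")) {
  edges <- utils::read.delim(file, comment.char = "#",
                             stringsAsFactors = FALSE)
  need <- c("from", "to", "rate", "glu_order")
  if (!all(need %in% names(edges))) {
    abort("NMDAr rate table must have columns from, to, rate, glu_order")
  }
  if (any(edges$rate < 0)) abort("NMDAr rate constants must be non-negative")
  states <- unique(c(edges$from, edges$to))
  if (!"o" %in% states) abort("scheme must contain an open state named 'o'")
  if (!"r" %in% states) abort("scheme must contain a resting state named 'r'")
  structure(
    list(states = states, edges = as_tibble(edges),
         open_state = match("o", states), resting_state = match("r", states)),
    class = "nmdar_scheme"
  )
}

#' Transition-rate generator matrix for a glutamate concentration
#'
#' Builds the generator `Q` such that `d n/dt = Q %*% n` for the state
#' occupancy vector `n`. Columns sum to zero, so occupancy is conserved.
#'
#' @param glu Glutamate concentration (mM), must be non-negative.
#' @param scheme An [nmdar_scheme()].
#' @return A square matrix (ms^-1) with state names on both dimensions.
#' @export
nmdar_rate_matrix <- function(glu, scheme = nmdar_scheme()) {
  if (!is.finite(glu) || glu < 0) abort("`glu` must be finite and >= 0 (mM)")
  ns <- length(scheme$states)
  Q <- matrix(0, ns, ns, dimnames = list(scheme$states, scheme$states))
  e <- scheme$edges
  k <- e$rate * ifelse(e$glu_order > 0, glu^e$glu_order, 1)
  for (i in seq_len(nrow(e))) {
    Q[e$to[i], e$from[i]] <- Q[e$to[i], e$from[i]] + k[i]
    Q[e$from[i], e$from[i]] <- Q[e$from[i], e$from[i]] - k[i]
  }
  Q
}

#' Time derivatives of NMDA receptor state occupancies
#'
#' @param occupancy Numeric vector of state occupancies (probabilities, in
#'   scheme state order).
#' @param glu Glutamate concentration (mM).
#' @param scheme An [nmdar_scheme()].
#' @return Occupancy rates (ms^-1); entries sum to zero.
#' @export
nmdar_derivatives <- function(occupancy, glu, scheme = nmdar_scheme()) {
  if (length(occupancy) != length(scheme$states)) {
    abort("`occupancy` length must match the number of scheme states")
  }
  if (any(occupancy < -1e-9) || any(occupancy > 1 + 1e-9)) {
    abort("`occupancy` entries must lie in [0, 1]")
  }
  drop(nmdar_rate_matrix(glu, scheme) %*% occupancy)
}

#' NMDA receptor conductance and magnesium-block parameters
#'
#' Parameters of the voltage-dependent magnesium block and the open-channel
#' conductance. The open conductance interpolates between `g1` (one
#' glutamate bound) and `g2` (two bound) with a logistic voltage dependence
#' of steepness `alpha`; the fraction of that conductance left unblocked by
#' external magnesium follows a Boltzmann factor with equilibrium constant
#' `k0` and electrical distance `delta`.
#'
#' `f_ca` is the calcium fraction of the NMDA receptor current (about 11% of
#' the total current is carried by calcium); `ca_scale` is a single
#' dimensionless calibration factor applied to the calcium current so the
#' assembled model's single-event response at resting potential peaks near
#' 0.9 uM. Both multiply the current; they are kept separate so the
#' physiological fraction stays legible.
#'
#' @param g1,g2 Open-channel conductances with one / two glutamate bound (pS).
#' @param alpha Steepness of the g1-g2 transition (mV^-1).
#' @param k0 Magnesium equilibrium constant (mM).
#' @param delta Electrical distance of the magnesium binding site (0-1).
#' @param n_receptors Number of NMDA receptors in the PSD.
#' @param f_ca Calcium fraction of the NMDAr current (0-1].
#' @param ca_scale Calibration scalar on the calcium current.
#' @return A list of class `nmdar_params`.
#' @export
nmdar_params <- function(g1 = 40, g2 = 247, alpha = 0.01, k0 = 3.57,
                         delta = 0.8, n_receptors = 20, f_ca = 0.11,
                         ca_scale = 1.199) {
  if (!(g2 > g1 && g1 > 0)) abort("need g2 > g1 > 0")
  if (f_ca <= 0 || f_ca > 1) abort("`f_ca` must lie in (0, 1]")
  structure(list(g1 = g1, g2 = g2, alpha = alpha, k0 = k0, delta = delta,
                 n_receptors = n_receptors, f_ca = f_ca, ca_scale = ca_scale),
            class = "nmdar_params")
}

#' Magnesium-unblocked single-channel conductance
#'
#' @param v Membrane potential (mV). Vectorized.
#' @param env An [ion_environment()] (supplies external magnesium).
#' @param p An [nmdar_params()].
#' @param k A [spine_constants()].
#' @return Conductance (pS); equals the magnesium-free conductance when
#'   `env$mg_out` is 0, and is bounded above by `g2`.
#' @examples
#' unblocked_conductance(0, ion_environment(mg_out = 0)) # (g1 + g2)/2
#' @export
unblocked_conductance <- function(v, env = ion_environment(),
                                  p = nmdar_params(), k = spine_constants()) {
  g0 <- p$g1 + (p$g2 - p$g1) / (1 + exp(p$alpha * v))
  vt <- 1000 * k$R * k$T / k$F # thermal voltage, mV
  g0 / (1 + (env$mg_out / p$k0) * exp(-p$delta * k$z * v / vt))
}

#' Total NMDA receptor conductance
#'
#' Open probability times the magnesium-unblocked single-channel conductance
#' times the receptor count.
#'
#' @param open_prob Open-state probability, in `[0, 1]`. Vectorized.
#' @inheritParams unblocked_conductance
#' @return Conductance (pS).
#' @export
nmdar_conductance <- function(open_prob, v, env = ion_environment(),
                              p = nmdar_params(), k = spine_constants()) {
  if (any(!is.finite(open_prob)) || any(open_prob < 0) || any(open_prob > 1)) {
    abort("`open_prob` must lie in [0, 1]")
  }
  unblocked_conductance(v, env, p, k) * open_prob * p$n_receptors
}

#' NMDA receptor calcium current
#'
#' Calcium component of the NMDAr current: conductance times the calcium
#' driving-force potential, scaled by the calcium fraction. Negative values
#' are inward (calcium entering the PSD).
#'
#' @param g_total Total NMDAr conductance (pS). Vectorized.
#' @param v_ca Calcium driving-force potential (mV), from
#'   [nernst_ca_potential()].
#' @param f_ca Calcium fraction of the current, in (0, 1].
#' @param ca_scale Calibration scalar (see [nmdar_params()]).
#' @return Current (pA).
#' @export
nmdar_calcium_current <- function(g_total, v_ca, f_ca = 0.11, ca_scale = 1) {
  if (f_ca <= 0 || f_ca > 1) abort("`f_ca` must lie in (0, 1]")
  1e-3 * ca_scale * f_ca * g_total * v_ca
}
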