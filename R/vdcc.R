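#' T-type voltage-dependent calcium channel parameters
#'
#' Single-channel conductance, number of channels recruited by a
#' backpropagating action potential, and the Hodgkin-Huxley-style gating rate
#' coefficients (activation gate `m`, inactivation gate `h`). Gating rate
#' functions follow the CA1 T-type formulation of Jaffe/Poirazi and are read
#' from a plain-text parameter table so they can be swapped.
#'
#' @param g_single Single-channel conductance (pS).
#' @param n_open Channels opened per backpropagating action potential.
#' @param file Path to the gating parameter table.
#' @return A list of class `ttype_params` with the gating coefficients
#'   spliced in.
#' @export
ttype_params <- function(g_single = 7.5, n_open = 5,
                         file = system.file("extdata", "vdcc_gating.tsv",
                                            package = "spinecal")) {
  if (g_single <= 0) abort("`g_single` must be positive (pS)")
  if (n_open < 1 || n_open > 20) {
    abort("`n_open` must lie in [1, 20] channels per spine")
  }
  tab <- utils::read.delim(file, comment.char = "#",
                           stringsAsFactors = FALSE)
  g <- as.list(setNames(tab$value, tab$param))
  structure(c(list(g_single = g_single, n_open = n_open), g),
            class = "ttype_params")
}

# x/(exp(x) - 1), stable near 0
.efun <- function(x) ifelse(abs(x) < 1e-5, 1 - x / 2, x / expm1(x))

#' T-type gating steady states and time constants
#'
#' @param v Membrane potential (mV). Vectorized.
#' @param p A [ttype_params()].
#' @return A tibble with columns `m_inf`, `tau_m` (ms), `h_inf`, `tau_h` (ms).
#' @export
vdcc_gating <- function(v, p = ttype_params()) {
  # alpha_m written via efun to stay finite at v = am_v0
  am <- p$am_a * p$am_k * .efun((p$am_v0 - v) / p$am_k)
  bm <- p$bm_a * exp(-v / p$bm_k)
  ah <- p$ah_a * exp(-v / p$ah_k)
  bh <- 1 / (exp((p$bh_v0 - v) / p$bh_k) + 1)
  tibble(m_inf = am / (am + bm), tau_m = 1 / (am + bm),
         h_inf = ah / (ah + bh), tau_h = 1 / (ah + bh))
}

#' T-type gating derivatives
#'
#' First-order relaxation of each gate toward its voltage-dependent steady
#' state: `dx/dt = (x_inf(v) - x) / tau_x(v)`.
#'
#' @param v Membrane potential (mV).
#' @param m,h Gating variables in `[0, 1]`.
#' @param p A [ttype_params()].
#' @return Named vector `c(dm, dh)` (ms^-1).
#' @export
vdcc_gating_derivatives <- function(v, m, h, p = ttype_params()) {
  if (any(c(m, h) < 0) || any(c(m, h) > 1)) {
    abort("`m` and `h` must lie in [0, 1]")
  }
  g <- vdcc_gating(v, p)
  c(dm = (g$m_inf - m) / g$tau_m, dh = (g$h_inf - h) / g$tau_h)
}

#' GHK-style driving term for the T-type current
#'
#' Concentration-dependent driving force (in mV) of the Goldman-Hodgkin-Katz
#' form used by the CA1 T-type formulation: it reduces to the linear driving
#' force far below the calcium reversal potential and rectifies as
#' intracellular calcium rises.
#'
#' @param v Membrane potential (mV). Vectorized.
#' @param ca_in Intracellular calcium (uM).
#' @param env An [ion_environment()].
#' @param k A [spine_constants()].
#' @return Driving potential (mV); negative means inward current.
#' @export
ghk_drive <- function(v, ca_in, env = ion_environment(),
                      k = spine_constants()) {
  f <- 25 * (k$T / 293.15) / 2  # RT/zF at T, in the 25 mV convention
  nu <- v / f
  ratio <- ca_in / (env$ca_out * 1000)
  -f * (1 - ratio * exp(nu)) * .efun(nu)
}

#' T-type calcium current
#'
#' `g_single * n_open * m^2 * h` times the GHK-style driving term. Negative
#' values are inward.
#'
#' @inheritParams ghk_drive
#' @param m,h Gating variables in `[0, 1]`.
#' @param p A [ttype_params()].
#' @return Current (pA).
#' @export
vdcc_current <- function(v, m, h, ca_in, env = ion_environment(),
                         p = ttype_params(), k = spine_constants()) {
  if (any(c(m, h) < 0) || any(c(m, h) > 1)) {
    abort("`m` and `h` must lie in [0, 1]")
  }
  1e-3 * p$g_single * p$n_open * m^2 * h * ghk_drive(v, ca_in, env, k)
}
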