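#' Calcium pump parameters (PMCA / NCX)
#'
#' Hill-equation extrusion parameters. The plasma-membrane calcium pump
#' (PMCA) is the high-affinity, low-capacity route with a fixed maximal
#' current; the sodium-calcium exchanger (NCX) is the steep (Hill 5),
#' low-affinity route whose maximal current is derived at run time from its
#' conductance and the 3Na:1Ca gradient potential.
#'
#' The PMCA half-max concentration is 1 uM (the value the efflux table and
#' text agree on; one summary table prints 0.1 uM instead, which can be
#' restored here). The NCX conductance is 0.0117 pS (one table prints 0.117;
#' 0.0117 matches the parameter listing and the source model).
#'
#' @param i_max Maximal PMCA extrusion current (pA). Ignored for NCX.
#' @param g_naca NCX conductance (pS). Ignored for PMCA.
#' @param K Half-max calcium concentration (uM).
#' @param h_c Hill coefficient.
#' @param kind `"pmca"` or `"ncx"`.
#' @return A list of class `pump_params`.
#' @export
pump_params <- function(kind = c("pmca", "ncx"), i_max = NULL, g_naca = NULL,
                        K = NULL, h_c = NULL) {
  kind <- match.arg(kind)
  if (kind == "pmca") {
    p <- list(kind = kind, i_max = i_max %||% 0.25, K = K %||% 1,
              h_c = h_c %||% 2)
  } else {
    p <- list(kind = kind, g_naca = g_naca %||% 0.0117, K = K %||% 1.5,
              h_c = h_c %||% 5)
  }
  if (p$K <= 0 || p$h_c <= 0) abort("`K` and `h_c` must be positive")
  structure(p, class = "pump_params")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.hill <- function(ca, K, h) ca^h / (K^h + ca^h)

#' PMCA extrusion current
#'
#' Hill-saturating pump current, efflux-positive and bounded by `i_max`.
#'
#' @param ca_in Spine calcium (uM), non-negative. Vectorized.
#' @param p A `pump_params("pmca")`.
#' @return Current (pA, efflux-positive).
#' @examples
#' pmca_current(1) # half of the 0.25 pA maximum
#' @export
pmca_current <- function(ca_in, p = pump_params("pmca")) {
  if (any(!is.finite(ca_in)) || any(ca_in < 0)) {
    abort("`ca_in` must be finite and non-negative (uM)")
  }
  p$i_max * .hill(ca_in, p$K, p$h_c)
}

#' NCX extrusion current
#'
#' Maximal current is `g_naca * |V_NaCa|` with the exchanger gradient
#' potential of [ncx_gradient_potential()], then scaled by a steep Hill term
#' (coefficient 5, half-max 1.5 uM): essentially silent at rest, strongly
#' recruited during large transients.
#'
#' @inheritParams pmca_current
#' @param env An [ion_environment()].
#' @param k A [spine_constants()].
#' @param p A `pump_params("ncx")`.
#' @return Current (pA, efflux-positive).
#' @export
ncx_current <- function(ca_in, env = ion_environment(),
                        p = pump_params("ncx"), k = spine_constants()) {
  i_max <- 1e-3 * p$g_naca * abs(ncx_gradient_potential(ca_in, env, k))
  i_max * .hill(ca_in, p$K, p$h_c)
}

#' Leak influx balancing the resting state
#'
#' A small constant calcium influx solved numerically so that the assembled
#' model has an exact fixed point at the resting concentration: with every
#' kinetic state at its resting equilibrium, the leak cancels the net resting
#' flux of the pumps, the resting T-type window current and the ER store.
#' Without it, pure efflux would drain the spine below the observed ~50 nM.
#'
#' @param config A [spine_config()].
#' @return Leak rate (uM ms^-1, may be small positive or negative).
#' @export
resting_leak_rate <- function(config) {
  ca <- config$init$ca
  env <- config$env
  k <- config$constants
  # pumps (efflux-positive currents)
  i_out <- pmca_current(ca, config$pmca) + ncx_current(ca, env, config$ncx, k)
  # resting T-type window current (inward-negative)
  g <- vdcc_gating(config$bap$v_rest, config$vdcc)
  i_vdcc <- vdcc_current(config$bap$v_rest, g$m_inf, g$h_inf, ca, env,
                         config$vdcc, k)
  j_mem <- current_to_rate(-(i_out + i_vdcc), config$geometry$v_spine, k)
  # ER store at its resting state
  st <- store_equilibrium(ca, config)
  j_er <- serca_flux(ca, st, config)$j + ryr_flux(ca, st, config)$j
  -(j_mem + j_er)
}
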