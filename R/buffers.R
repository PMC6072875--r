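#' Calcium buffer parameters
#'
#' Three buffer pools slow and shape the free-calcium response:
#'
#' * **Calmodulin** (`cam_params()`): a cooperative buffer binding three
#'   calcium ions in one step (`CaM + 3 Ca <-> CaM.Ca3`), Hill order 3.
#' * **Generic calcium-binding proteins** (`cbp_params()`): a 1:1 mass-action
#'   pool lumping all buffers other than calmodulin and calbindin.
#' * **Calbindin-D28k** (`calbindin_params()`): four binding sites in two
#'   independent classes (2 high-affinity + 2 medium-affinity), tracked as a
#'   9-state occupancy lattice indexed by (high sites bound, medium sites
#'   bound). Per-site rates are read from a plain-text table.
#'
#' Totals are given in mM as usually tabulated and converted to the package's
#' internal uM convention; rate constants are converted likewise. The
#' calmodulin forward rate default reads the tabulated "10e7 /mM^3 ms"
#' literally as 1e8 mM^-3 ms^-1.
#'
#' @param total Total buffer concentration (mM).
#' @param h_c Cooperativity order (calmodulin only).
#' @param k_f Forward rate (mM^-h ms^-1).
#' @param k_r Reverse rate (ms^-1).
#' @param file Calbindin per-site rate table.
#' @return A parameter list of class `buffer_params`.
#' @name buffer_params
NULL

#' @rdname buffer_params
#' @export
cam_params <- function(total = 0.01, h_c = 3, k_f = 1e8, k_r = 10) {
  structure(list(kind = "cam", total = total * 1e3, h_c = h_c,
                 k_f = k_f * (1e-3)^h_c, k_r = k_r),  # to uM^-h ms^-1
            class = "buffer_params")
}

#' @rdname buffer_params
#' @export
cbp_params <- function(total = 0.8, k_f = 247, k_r = 4) {
  structure(list(kind = "cbp", total = total * 1e3, h_c = 1,
                 k_f = k_f * 1e-3, k_r = k_r),
            class = "buffer_params")
}

#' @rdname buffer_params
#' @export
calbindin_params <- function(total = 0.045,
                             file = system.file("extdata",
                                                "calbindin_rates.tsv",
                                                package = "spinecal")) {
  tab <- utils::read.delim(file, comment.char = "#",
                           stringsAsFactors = FALSE)
  hi <- tab[tab$site_class == "high", ]
  me <- tab[tab$site_class == "medium", ]
  structure(list(kind = "calbindin", total = total * 1e3,
                 kon_h = hi$kon * 1e-3, koff_h = hi$koff,
                 kon_m = me$kon * 1e-3, koff_m = me$koff),
            class = "buffer_params")
}

#' Equilibrium buffer state at a clamped calcium concentration
#'
#' @param ca_in Free calcium (uM).
#' @param config A [spine_config()].
#' @return A list with `cam_bound` (uM), `cbp_bound` (uM) and `calbindin`
#'   (9 occupancy fractions, high-bound-major order).
#' @export
buffer_equilibrium <- function(ca_in, config = spine_config()) {
  cam <- config$cam
  cbp <- config$cbp
  cb <- config$calbindin
  cam_b <- cam$total * cam$k_f * ca_in^cam$h_c /
    (cam$k_f * ca_in^cam$h_c + cam$k_r)
  cbp_b <- cbp$total * cbp$k_f * ca_in / (cbp$k_f * ca_in + cbp$k_r)
  p_h <- ca_in / (ca_in + cb$koff_h / cb$kon_h)
  p_m <- ca_in / (ca_in + cb$koff_m / cb$kon_m)
  x <- outer(stats::dbinom(0:2, 2, p_h), stats::dbinom(0:2, 2, p_m))
  list(cam_bound = cam_b, cbp_bound = cbp_b,
       calbindin = as.vector(t(x)))  # index = 3*high + med + 1
}

#' Buffer reaction fluxes
#'
#' Mass-action rates for all three buffer pools at the current state, and the
#' resulting net rate on free calcium (negative while buffers are loading).
#' Stoichiometry: 3 calcium per calmodulin complex, 1 per CBP site, 1 per
#' occupied calbindin site.
#'
#' @param ca_in Free calcium (uM).
#' @param state Buffer state as returned by [buffer_equilibrium()].
#' @param config A [spine_config()].
#' @return A list with `j` (net free-calcium rate, uM ms^-1), `d_cam`,
#'   `d_cbp` (uM ms^-1) and `d_calbindin` (9 occupancy rates, ms^-1).
#' @export
buffer_fluxes <- function(ca_in, state, config = spine_config()) {
  cam <- config$cam
  cbp <- config$cbp
  cb <- config$calbindin
  if (state$cam_bound < -1e-9 || state$cam_bound > cam$total + 1e-9 ||
      state$cbp_bound < -1e-9 || state$cbp_bound > cbp$total + 1e-9 ||
      any(state$calbindin < -1e-9) || any(state$calbindin > 1 + 1e-9)) {
    abort("buffer state outside its admissible range")
  }
  d_cam <- cam$k_f * (cam$total - state$cam_bound) * ca_in^cam$h_c -
    cam$k_r * state$cam_bound
  d_cbp <- cbp$k_f * (cbp$total - state$cbp_bound) * ca_in -
    cbp$k_r * state$cbp_bound

  x <- matrix(state$calbindin, 3, 3, byrow = TRUE)  # [high+1, med+1]
  dx <- matrix(0, 3, 3)
  bind <- 0
  for (i in 0:2) {
    for (j in 0:2) {
      # high-affinity site transitions
      f_h <- (2 - i) * cb$kon_h * ca_in * x[i + 1, j + 1]
      b_h <- i * cb$koff_h * x[i + 1, j + 1]
      # medium-affinity site transitions
      f_m <- (2 - j) * cb$kon_m * ca_in * x[i + 1, j + 1]
      b_m <- j * cb$koff_m * x[i + 1, j + 1]
      dx[i + 1, j + 1] <- dx[i + 1, j + 1] - f_h - b_h - f_m - b_m
      if (i < 2) dx[i + 2, j + 1] <- dx[i + 2, j + 1] + f_h
      if (i > 0) dx[i, j + 1] <- dx[i, j + 1] + b_h
      if (j < 2) dx[i + 1, j + 2] <- dx[i + 1, j + 2] + f_m
      if (j > 0) dx[i + 1, j] <- dx[i + 1, j] + b_m
      bind <- bind + f_h + f_m - b_h - b_m
    }
  }
  j_free <- -(cam$h_c * d_cam + d_cbp + cb$total * bind)
  list(j = j_free, d_cam = d_cam, d_cbp = d_cbp,
       d_calbindin = as.vector(t(dx)))
}

#' Calcium bound to buffers, stoichiometry-weighted
#'
#' @param state Buffer state as returned by [buffer_equilibrium()].
#' @param config A [spine_config()].
#' @return Bound calcium (uM of spine volume).
#' @export
buffer_bound_calcium <- function(state, config = spine_config()) {
  sites <- sum(state$calbindin * (rep(0:2, each = 3) + rep(0:2, 3)))
  config$cam$h_c * state$cam_bound + state$cbp_bound +
    config$calbindin$total * sites
}

#' Fraction of spine calcium bound to buffers at rest
#'
#' Equilibrates all three buffers at the resting free-calcium concentration
#' and reports `100 * bound / (bound + free)`.
#'
#' @param config A [spine_config()].
#' @param ca_in Free calcium (uM); defaults to the configured resting value.
#' @return Percent bound.
#' @export
buffered_fraction <- function(config = spine_config(), ca_in = config$init$ca) {
  st <- buffer_equilibrium(ca_in, config)
  bound <- buffer_bound_calcium(st, config)
  100 * bound / (bound + ca_in)
}

#' ER store parameters
#'
#' The spine's intracellular calcium store: a 2-state SERCA uptake pump
#' (cytosol-facing / lumen-facing, binding two calcium per cycle) and a
#' calcium-induced calcium release (CICR) ryanodine-receptor gate with a
#' fourth-power calcium activation. ER lumenal calcium is held constant.
#' Only a minority (~19%) of CA1 spines contain ER, so the store can be
#' disabled; it is enabled by default, matching the validated model.
#'
#' @param enabled Logical; disabled stores contribute zero flux.
#' @param ca_er ER lumenal calcium (uM), constant.
#' @param serca_k1 SERCA forward (binding) rate (uM^-2 ms^-1).
#' @param serca_k2 SERCA turnover (release-to-lumen) rate (ms^-1).
#' @param serca_rho SERCA transport capacity scale (uM).
#' @param ryr_ko RyR opening rate coefficient (uM^-4 ms^-1).
#' @param ryr_kc RyR closing rate (ms^-1).
#' @param ryr_nu RyR release rate per unit gradient (ms^-1).
#' @return A list of class `er_store_params`.
#' @export
er_store_params <- function(enabled = TRUE, ca_er = 250,
                            serca_k1 = 1e-4, serca_k2 = 0.2, serca_rho = 1,
                            ryr_ko = 1e-4, ryr_kc = 0.5, ryr_nu = 5e-5) {
  structure(list(enabled = enabled, ca_er = ca_er, serca_k1 = serca_k1,
                 serca_k2 = serca_k2, serca_rho = serca_rho, ryr_ko = ryr_ko,
                 ryr_kc = ryr_kc, ryr_nu = ryr_nu),
            class = "er_store_params")
}

#' ER store equilibrium state at clamped calcium
#'
#' @param ca_in Free calcium (uM).
#' @param config A [spine_config()].
#' @return List with `serca_s2` (lumen-facing pump fraction) and `ryr_open`.
#' @export
store_equilibrium <- function(ca_in, config = spine_config()) {
  er <- config$er
  a <- er$serca_k1 * ca_in^2
  o <- er$ryr_ko * ca_in^4
  list(serca_s2 = a / (a + er$serca_k2), ryr_open = o / (o + er$ryr_kc))
}

#' SERCA uptake flux
#'
#' Two-state pump: calcium binds the cytosol-facing state (removing free
#' calcium), then the pump turns over and delivers it to the lumen. Uptake is
#' never positive; a disabled store returns zeros.
#'
#' @param ca_in Free calcium (uM).
#' @param state Store state as from [store_equilibrium()].
#' @param config A [spine_config()].
#' @return List with `j` (free-calcium rate, uM ms^-1, <= 0), `d_s2` (pump
#'   state rate, ms^-1) and `j_er` (rate of delivery to the lumen, in spine
#'   uM ms^-1, for mass bookkeeping).
#' @export
serca_flux <- function(ca_in, state, config = spine_config()) {
  er <- config$er
  if (!er$enabled) return(list(j = 0, d_s2 = 0, j_er = 0))
  f <- er$serca_k1 * ca_in^2 * (1 - state$serca_s2)
  b <- er$serca_k2 * state$serca_s2
  list(j = -2 * er$serca_rho * f, d_s2 = f - b, j_er = 2 * er$serca_rho * b)
}

#' Ryanodine-receptor release flux
#'
#' Calcium-induced calcium release: the open fraction relaxes toward a steep
#' (4th-power) function of cytosolic calcium, and open receptors pass calcium
#' down the lumen-to-cytosol gradient.
#'
#' @inheritParams serca_flux
#' @return List with `j` (free-calcium rate, uM ms^-1, >= 0 while the lumen
#'   is fuller than the cytosol) and `d_open` (gating rate, ms^-1).
#' @export
ryr_flux <- function(ca_in, state, config = spine_config()) {
  er <- config$er
  if (!er$enabled) return(list(j = 0, d_open = 0))
  d_open <- er$ryr_ko * ca_in^4 * (1 - state$ryr_open) -
    er$ryr_kc * state$ryr_open
  list(j = er$ryr_nu * state$ryr_open * (er$ca_er - ca_in), d_open = d_open)
}
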