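#' Physical constants for electro-diffusion calculations
#'
#' Faraday's constant, the molar gas constant, absolute temperature and the
#' calcium valence used by every driving-force and current-to-concentration
#' conversion in the package. The defaults are the values used throughout the
#' spine model (near-physiological temperature, 299.5 K).
#'
#' @param F Faraday constant (C mol^-1).
#' @param R Molar gas constant (J mol^-1 K^-1).
#' @param T Absolute temperature (K).
#' @param z Valence of the calcium ion (dimensionless).
#'
#' @return A list of class `spine_constants`.
#' @examples
#' k <- spine_constants()
#' # thermal voltage RT/F, mV
#' 1000 * k$R * k$T / k$F
#' @export
spine_constants <- function(F = 96486.7, R = 8.31434, T = 299.5, z = 2) {
  vals <- c(F = F, R = R, T = T, z = z)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    abort("all physical constants must be finite and strictly positive")
  }
  structure(list(F = F, R = R, T = T, z = z), class = "spine_constants")
}

#' Spine/PSD geometry
#'
#' Geometry of the two-compartment spine model: the spine head and the much
#' smaller postsynaptic density (PSD) sub-compartment that exchanges calcium
#' with it by diffusion. Volumes are those of an average CA1 mushroom spine
#' (0.1 um^3) and its PSD (0.0032 um^3). `a` is the PSD-spine interface area,
#' `d` the distance between the compartment midpoints, and `D` the cytosolic
#' calcium diffusion coefficient. `d` defaults to the midpoint distance of a
#' thin cylindrical PSD sitting on a spherical head with the default volumes;
#' `D` defaults to a typical free-calcium diffusion coefficient.
#'
#' @param v_spine Spine head volume (um^3).
#' @param v_psd PSD volume (um^3), must be smaller than `v_spine`.
#' @param a PSD-spine interface area (um^2).
#' @param d Distance between compartment midpoints (um).
#' @param D Calcium diffusion coefficient (um^2 ms^-1).
#'
#' @return A list of class `spine_geometry`.
#' @export
spine_geometry <- function(v_spine = 0.1, v_psd = 0.0032, a = 0.132,
                           d = 0.24, D = 0.22) {
  vals <- c(v_spine = v_spine, v_psd = v_psd, a = a, d = d, D = D)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    abort("all geometry fields must be finite and strictly positive")
  }
  if (v_psd >= v_spine) abort("`v_psd` must be smaller than `v_spine`")
  structure(as.list(vals), class = "spine_geometry")
}

#' Fixed extracellular / intracellular ion concentrations
#'
#' Ion concentrations held constant during a simulation: extracellular
#' calcium and magnesium, and intra/extracellular sodium (needed by the
#' sodium-calcium exchanger gradient term). All in mM.
#'
#' @param ca_out Extracellular calcium (mM).
#' @param na_in Intracellular sodium (mM).
#' @param na_out Extracellular sodium (mM).
#' @param mg_out Extracellular magnesium (mM).
#'
#' @return A list of class `ion_environment`.
#' @export
ion_environment <- function(ca_out = 2, na_in = 10, na_out = 140, mg_out = 1) {
  vals <- c(ca_out = ca_out, na_in = na_in, na_out = na_out, mg_out = mg_out)
  if (any(!is.finite(vals)) || any(vals < 0) || ca_out <= 0 || na_in <= 0 ||
      na_out <= 0) {
    abort("ion concentrations must be finite and positive (mg_out may be 0)")
  }
  structure(as.list(vals), class = "ion_environment")
}

#' Calcium driving-force potential
#'
#' Nernst-style potential for calcium between the extracellular space and the
#' spine head, used as the driving force of the NMDA receptor calcium
#' current. The logarithm is base 10 *without* the usual ln(10) factor: that
#' is the form whose values match the model's own calibration points
#' (about -60 mV at 50 nM and -30 mV at 10 uM intracellular calcium with 2 mM
#' outside), so it is kept deliberately.
#'
#' @param ca_in Intracellular (spine) calcium, uM. Vectorized.
#' @param env An [ion_environment()].
#' @param k A [spine_constants()].
#'
#' @return Potential in mV (negative for physiological inward gradients).
#' @examples
#' nernst_ca_potential(0.05) # ~ -60 mV
#' nernst_ca_potential(10)   # ~ -30 mV
#' @export
nernst_ca_potential <- function(ca_in, env = ion_environment(),
                                k = spine_constants()) {
  if (any(!is.finite(ca_in)) || any(ca_in <= 0)) {
    abort("`ca_in` must be finite and strictly positive (uM)")
  }
  ca_out_um <- env$ca_out * 1000
  -(1000 * k$R * k$T / (k$z * k$F)) * log10(ca_out_um / ca_in)
}

#' Sodium-calcium exchange gradient potential
#'
#' Combined electrochemical gradient driving the 3 Na+ : 1 Ca2+ exchanger,
#' `(RT/F) * (3 ln([Na]o/[Na]i) - ln([Ca]o/[Ca]i))` in mV (natural log, as
#' distinct from the base-10 convention of [nernst_ca_potential()]).
#'
#' @inheritParams nernst_ca_potential
#' @return Potential in mV. Strictly increasing in `ca_in`.
#' @export
ncx_gradient_potential <- function(ca_in, env = ion_environment(),
                                   k = spine_constants()) {
  if (any(!is.finite(ca_in)) || any(ca_in <= 0)) {
    abort("`ca_in` must be finite and strictly positive (uM)")
  }
  ca_out_um <- env$ca_out * 1000
  (1000 * k$R * k$T / k$F) *
    (3 * log(env$na_out / env$na_in) - log(ca_out_um / ca_in))
}

#' PSD-spine diffusion rates
#'
#' First-order diffusive exchange between the PSD sub-compartment and the
#' spine head. Returns the concentration rate each compartment sees; the
#' volume-weighted sum is exactly zero (calcium mass is conserved by
#' diffusion).
#'
#' @param ca_psd PSD calcium (uM). Vectorized.
#' @param ca_spine Spine calcium (uM). Vectorized.
#' @param geom A [spine_geometry()].
#'
#' @return A tibble with columns `spine` and `psd`, both uM ms^-1.
#' @export
psd_diffusion_rates <- function(ca_psd, ca_spine, geom = spine_geometry()) {
  grad <- ca_psd - ca_spine
  g <- geom$D * geom$a / geom$d
  tibble(spine = g / geom$v_spine * grad, psd = -g / geom$v_psd * grad)
}

#' Convert a calcium current into a concentration rate
#'
#' `i / (z F V)` with unit bookkeeping for pA, um^3, uM and ms: 1 pA of
#' calcium current into a 0.1 um^3 compartment moves total calcium at about
#' 51.8 uM ms^-1 (before any buffering). Sign is preserved, so pass
#' efflux-positive currents negated.
#'
#' @param i_ca Calcium current (pA). Vectorized.
#' @param volume Compartment volume (um^3).
#' @param k A [spine_constants()].
#'
#' @return Concentration rate, uM ms^-1.
#' @export
current_to_rate <- function(i_ca, volume, k = spine_constants()) {
  if (!is.finite(volume) || volume <= 0) {
    abort("`volume` must be finite and strictly positive (um^3)")
  }
  1e6 * i_ca / (k$z * k$F * volume)
}
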