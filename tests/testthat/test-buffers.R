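cfg <- spine_config()

test_that("all buffer fluxes vanish at equilibrium", {
  for (ca in c(0.05, 0.5, 5)) {
    st <- buffer_equilibrium(ca, cfg)
    fl <- buffer_fluxes(ca, st, cfg)
    expect_equal(fl$j, 0, tolerance = 1e-9)
    expect_equal(fl$d_cam, 0, tolerance = 1e-10)
    expect_equal(fl$d_cbp, 0, tolerance = 1e-10)
    expect_equal(fl$d_calbindin, rep(0, 9), tolerance = 1e-10)
  }
})

test_that("buffer fluxes conserve total calcium and calbindin protein", {
  set.seed(11)
  for (i in 1:15) {
    ca <- runif(1, 0.01, 20)
    x <- runif(9); x <- x / sum(x)
    st <- list(cam_bound = runif(1, 0, cfg$cam$total),
               cbp_bound = runif(1, 0, cfg$cbp$total),
               calbindin = x)
    fl <- buffer_fluxes(ca, st, cfg)
    sites <- rep(0:2, each = 3) + rep(0:2, 3)
    bound_rate <- cfg$cam$h_c * fl$d_cam + fl$d_cbp +
      cfg$calbindin$total * sum(fl$d_calbindin * sites)
    # calcium leaving solution equals calcium appearing on buffers
    expect_equal(fl$j + bound_rate, 0, tolerance = 1e-9)
    # occupancy-lattice probability is conserved
    expect_equal(sum(fl$d_calbindin), 0, tolerance = 1e-12)
  }
  bad <- list(cam_bound = -1, cbp_bound = 0, calbindin = rep(1 / 9, 9))
  expect_error(buffer_fluxes(0.05, bad, cfg), "range")
})

test_that("resting bound fraction matches the closed-form equilibrium", {
  # closed form: each pool at its binding isotherm at 50 nM
  ca <- 0.05
  cbp_b <- cfg$cbp$total * ca / (ca + cfg$cbp$k_r / cfg$cbp$k_f)
  p_h <- ca / (ca + cfg$calbindin$koff_h / cfg$calbindin$kon_h)
  p_m <- ca / (ca + cfg$calbindin$koff_m / cfg$calbindin$kon_m)
  cb_b <- cfg$calbindin$total * 2 * (p_h + p_m)
  cam_b <- cfg$cam$total * cfg$cam$k_f * ca^3 /
    (cfg$cam$k_f * ca^3 + cfg$cam$k_r)
  expected <- 100 * (3 * cam_b + cbp_b + cb_b) /
    (3 * cam_b + cbp_b + cb_b + ca)
  expect_equal(buffered_fraction(cfg), expected, tolerance = 1e-9)
  # the overwhelming majority of resting spine calcium is buffer-bound
  expect_gt(buffered_fraction(cfg), 90)
})

test_that("SERCA uptake is non-positive, zero at zero calcium, monotone", {
  st <- store_equilibrium(0.05, cfg)
  expect_equal(serca_flux(0, list(serca_s2 = 0, ryr_open = 0), cfg)$j, 0)
  up <- vapply(c(0.05, 0.5, 2, 10),
               function(ca) -serca_flux(ca, st, cfg)$j, numeric(1))
  expect_true(all(up >= 0))
  expect_true(all(diff(up) > 0))
  # analytic fixed point of the 2-state pump at rest
  er <- cfg$er
  a <- er$serca_k1 * 0.05^2
  s2_star <- a / (a + er$serca_k2)
  expect_equal(store_equilibrium(0.05, cfg)$serca_s2, s2_star)
  expect_equal(serca_flux(0.05, store_equilibrium(0.05, cfg), cfg)$j,
               -2 * er$serca_rho * a * (1 - s2_star))
  off <- spine_config(er = er_store_params(enabled = FALSE))
  expect_equal(serca_flux(5, st, off)$j, 0)
})

test_that("RyR release is calcium-induced and gradient-driven", {
  st_rest <- store_equilibrium(0.05, cfg)
  st_high <- store_equilibrium(10, cfg)
  expect_lt(st_rest$ryr_open, 1e-6)
  expect_gt(st_high$ryr_open / max(st_rest$ryr_open, 1e-300), 1e3)
  # no lumen-cytosol gradient, no release
  cfg_eq <- spine_config(er = er_store_params(ca_er = 10))
  expect_equal(ryr_flux(10, st_high, cfg_eq)$j, 0)
  # gating step response matches a fine-step reference integration
  er <- cfg$er
  w <- 0
  dt <- 1e-3
  for (i in seq_len(20000)) {  # 20 ms at 10 uM
    w <- w + dt * (er$ryr_ko * 10^4 * (1 - w) - er$ryr_kc * w)
  }
  k_on <- er$ryr_ko * 10^4
  w_exact <- k_on / (k_on + er$ryr_kc) * (1 - exp(-(k_on + er$ryr_kc) * 20))
  expect_equal(w, w_exact, tolerance = 1e-4)
})

test_that("removing the buffers raises the single-event peak", {
  cfg_fast <- test_config()
  base <- peak_amplitude(single_pre_event(cfg_fast, t_max = 400))
  nobuf <- spine_config(
    record_dt = 0.1,
    cam = cam_params(total = 1e-9),
    cbp = cbp_params(total = 1e-9),
    calbindin = calbindin_params(total = 1e-9))
  expect_gt(peak_amplitude(single_pre_event(nobuf, t_max = 400)), base)
})
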