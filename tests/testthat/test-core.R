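test_that("calcium driving-force potential matches its calibration points", {
  expect_equal(nernst_ca_potential(0.05), -60, tolerance = 0.011)
  expect_equal(nernst_ca_potential(10), -30, tolerance = 0.011)
  # equal concentrations inside and out: no gradient, no potential
  expect_equal(nernst_ca_potential(2000, ion_environment(ca_out = 2)), 0)
})

test_that("driving-force potential is monotone and antisymmetric", {
  ca <- c(0.01, 0.05, 0.5, 5, 50)
  v <- nernst_ca_potential(ca)
  expect_true(all(diff(v) > 0))
  # swapping intra/extracellular roles flips the sign
  env_swap <- ion_environment(ca_out = 0.05 / 1000)
  expect_equal(nernst_ca_potential(2000, env_swap),
               -nernst_ca_potential(0.05))
  expect_error(nernst_ca_potential(-1), "positive")
})

test_that("NCX gradient potential matches hand evaluation and limits", {
  # (RT/F)(3 ln 14 - ln 40000) with RT/F ~ 25.8 mV
  k <- spine_constants()
  vt <- 1000 * k$R * k$T / k$F
  expect_equal(ncx_gradient_potential(0.05),
               vt * (3 * log(14) - log(40000)), tolerance = 1e-12)
  expect_lt(abs(ncx_gradient_potential(0.05) - (-69)), 0.5)
  # no gradients, no potential
  env0 <- ion_environment(ca_out = 2, na_in = 140, na_out = 140)
  expect_equal(ncx_gradient_potential(2000, env0), 0)
  v <- ncx_gradient_potential(c(0.05, 0.5, 5))
  expect_true(all(diff(v) > 0))
})

test_that("PSD diffusion conserves calcium mass for arbitrary states", {
  geom <- spine_geometry()
  set.seed(42)
  for (i in 1:20) {
    ca_psd <- runif(1, 0, 100)
    ca_sp <- runif(1, 0, 100)
    r <- psd_diffusion_rates(ca_psd, ca_sp, geom)
    expect_equal(geom$v_spine * r$spine + geom$v_psd * r$psd, 0,
                 tolerance = 1e-12)
  }
  expect_equal(unlist(psd_diffusion_rates(0.3, 0.3, geom)),
               c(spine = 0, psd = 0))
  # direct formula evaluation
  r <- psd_diffusion_rates(10, 0.05, geom)
  expect_equal(r$spine, geom$D * geom$a / (geom$d * geom$v_spine) * 9.95)
})

test_that("current-to-rate conversion has the right magnitude and scaling", {
  expect_equal(current_to_rate(1, 0.1), 51.8, tolerance = 1e-3)
  expect_equal(current_to_rate(0, 0.1), 0)
  # linear in current, inverse in volume
  expect_equal(current_to_rate(3, 0.1), 3 * current_to_rate(1, 0.1))
  expect_equal(current_to_rate(1, 0.2), current_to_rate(1, 0.1) / 2)
  expect_error(current_to_rate(1, 0), "positive")
})

test_that("geometry and environment constructors validate their inputs", {
  expect_error(spine_geometry(v_psd = 0.2), "smaller")
  expect_error(spine_geometry(a = -1), "positive")
  expect_error(ion_environment(ca_out = 0), "positive")
  expect_error(spine_constants(T = -1), "positive")
})
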