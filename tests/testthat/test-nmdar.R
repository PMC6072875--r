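scheme <- nmdar_scheme()

test_that("the kinetic scheme is well-formed and conservative", {
  expect_length(scheme$states, 8)
  expect_true(all(scheme$edges$rate >= 0))
  for (glu in c(0, 0.3, 1)) {
    Q <- nmdar_rate_matrix(glu, scheme)
    expect_equal(colSums(Q), setNames(numeric(8), scheme$states),
                 tolerance = 1e-12)
  }
  expect_error(nmdar_rate_matrix(-1, scheme), "0")
})

test_that("occupancy derivatives conserve probability and rest is absorbing", {
  rest <- as.numeric(scheme$states == "r")
  expect_equal(nmdar_derivatives(rest, 0, scheme), setNames(numeric(8), scheme$states))
  set.seed(7)
  for (i in 1:25) {
    occ <- runif(8)
    occ <- occ / sum(occ)
    glu <- runif(1, 0, 2)
    expect_equal(sum(nmdar_derivatives(occ, glu, scheme)), 0,
                 tolerance = 1e-12)
  }
})

test_that("pulse response matches a matrix-exponential reference", {
  skip_if_not_installed("Matrix")
  rest <- as.numeric(scheme$states == "r")
  # 1 ms at 1 mM, then 50 ms of decay, via exact matrix exponentials
  occ_pulse <- expm_occupancy(rest, 1, 1, scheme)
  occ_after <- expm_occupancy(occ_pulse, 0, 50, scheme)
  # fine fixed-step reference integration of the same rate equations
  step_integrate <- function(occ, glu, dur, dt = 1e-3) {
    Q <- nmdar_rate_matrix(glu, scheme)
    for (i in seq_len(round(dur / dt))) {
      k1 <- Q %*% occ
      k2 <- Q %*% (occ + dt / 2 * k1)
      k3 <- Q %*% (occ + dt / 2 * k2)
      k4 <- Q %*% (occ + dt * k3)
      occ <- occ + dt / 6 * drop(k1 + 2 * k2 + 2 * k3 + k4)
    }
    occ
  }
  occ_num <- step_integrate(step_integrate(rest, 1, 1), 0, 50)
  expect_equal(unname(occ_num), unname(occ_after), tolerance = 1e-8)
  expect_gt(occ_pulse[scheme$open_state], 0)
  # occupancies stay inside the probability simplex
  expect_true(all(occ_pulse >= 0 & occ_pulse <= 1))
  expect_equal(sum(occ_pulse), 1, tolerance = 1e-10)
})

test_that("open probability decays monotonically once glutamate is gone", {
  skip_if_not_installed("Matrix")
  rest <- as.numeric(scheme$states == "r")
  occ <- expm_occupancy(rest, 1, 1, scheme)
  # let gating settle past its early rise, then check monotone decay
  occ <- expm_occupancy(occ, 0, 20, scheme)
  po <- numeric(30)
  for (i in seq_along(po)) {
    occ <- expm_occupancy(occ, 0, 10, scheme)
    po[i] <- occ[scheme$open_state]
  }
  expect_true(all(diff(po) < 0))
  expect_lt(po[length(po)], 0.01)
})

test_that("magnesium block follows the two-factor conductance model", {
  p <- nmdar_params()
  no_mg <- ion_environment(mg_out = 0)
  # logistic midpoint at 0 mV without magnesium
  expect_equal(unblocked_conductance(0, no_mg, p), (p$g1 + p$g2) / 2)
  # hyperpolarized limit reaches the two-glutamate conductance
  expect_equal(unblocked_conductance(-1e4, no_mg, p), p$g2, tolerance = 1e-6)
  # 1 mM magnesium at -65 mV blocks ~94% of the channels
  k <- spine_constants()
  g0_65 <- unblocked_conductance(-65, no_mg, p)
  frac <- unblocked_conductance(-65, ion_environment(), p) / g0_65
  vt <- 1000 * k$R * k$T / k$F
  expect_equal(frac, 1 / (1 + (1 / p$k0) * exp(0.8 * 2 * 65 / vt)),
               tolerance = 1e-12)
  expect_equal(frac, 0.06, tolerance = 0.01)
  # bounded by g2 and non-negative everywhere; increasing with
  # depolarization over the physiological sub-reversal range (above ~+20 mV
  # the declining two-glutamate interpolation outweighs further unblock)
  v <- seq(-90, 40, by = 1)
  g <- unblocked_conductance(v, ion_environment(), p)
  expect_true(all(g > 0 & g <= p$g2))
  expect_true(all(diff(g[v <= 20]) > 0))
})

test_that("total conductance and calcium current compose linearly", {
  p <- nmdar_params()
  no_mg <- ion_environment(mg_out = 0)
  expect_equal(nmdar_conductance(0, -65, p = p), 0)
  expect_equal(nmdar_conductance(1, 0, no_mg, p), 143.5 * 20)
  expect_equal(nmdar_conductance(0.4, -30, p = p),
               2 * nmdar_conductance(0.2, -30, p = p))
  expect_error(nmdar_conductance(1.2, 0), "\\[0, 1\\]")
  expect_equal(nmdar_calcium_current(0, -60), 0)
  expect_equal(nmdar_calcium_current(100, 0), 0)
  # inward (negative) for physiological driving force
  expect_lt(nmdar_calcium_current(100, -60), 0)
  expect_equal(nmdar_calcium_current(100, -60, f_ca = 0.11),
               1e-3 * 0.11 * 100 * -60)
})
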