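test_that("calcium mass bookkeeping closes to 1e-9 through a stimulus", {
  cfg <- test_config()
  rec <- run_simulation(cfg, pre = 20, post = 23, t_max = 300)
  y_end <- attr(rec, "final_state")
  total_end <- state_total_ca(y_end, cfg)
  total_start <- state_total_ca(initial_state(cfg), cfg)
  # free + bound + ER-sequestered must track the transmembrane fluxes
  balance <- total_end + y_end["cum_er"] - y_end["cum_in"] - total_start
  expect_lt(abs(balance) / total_end, 1e-9)
})

test_that("kinetic states stay in the probability simplex during transients", {
  cfg <- test_config()
  # strong stimulus: three pre events with coincident bAPs
  res <- .Machine$double.eps
  rec <- run_simulation(cfg, pre = c(20, 60, 100), post = c(23, 63, 103),
                        t_max = 400)
  y_end <- attr(rec, "final_state")
  ns <- length(cfg$scheme$states)
  occ <- y_end[3:(2 + ns)]
  expect_true(all(occ >= -1e-6 & occ <= 1 + 1e-6))
  expect_equal(sum(occ), 1, tolerance = 1e-9)
  expect_true(all(y_end[c("m", "h")] >= 0 & y_end[c("m", "h")] <= 1))
  cb <- y_end[grep("^cb_", names(y_end))]
  expect_true(all(cb >= -1e-6 & cb <= 1 + 1e-6))
  expect_equal(sum(cb), 1, tolerance = 1e-9)
  expect_true(all(rec$open >= 0 & rec$open <= 1 + 1e-9))
})

test_that("compiled integrator agrees with the adaptive reference solver", {
  cfg <- test_config()
  cfg_l <- spine_config(method = "lsoda")
  rA <- run_simulation(cfg, pre = 20, post = 25, t_max = 120)
  rB <- run_simulation(cfg_l, pre = 20, post = 25, t_max = 120)
  i <- match(round(rB$time, 6), round(rA$time, 6))
  expect_true(all(!is.na(i)))
  err <- max(abs(rA$ca_spine[i] - rB$ca_spine)) / max(rB$ca_spine)
  expect_lt(err, 1e-3)
})

test_that("halving the step changes the single-event peak by far less than 1%", {
  p1 <- peak_amplitude(single_pre_event(test_config(), t_max = 400))
  p2 <- peak_amplitude(single_pre_event(test_config(dt = 0.0025),
                                        t_max = 400))
  expect_lt(abs(p1 - p2) / p1, 0.01)
})

test_that("peak_amplitude handles windows, baselines and errors", {
  rec <- tibble::tibble(time = 0:10,
                        ca_spine = c(rep(1, 5), 7, rep(1, 5)))
  expect_equal(peak_amplitude(rec), 7)
  expect_equal(peak_amplitude(rec, baseline = "first"), 6)
  expect_equal(peak_amplitude(rec, window = c(7, 10)), 1)
  expect_equal(peak_amplitude(rec, baseline = 1, window = c(0, 4)), 0)
  expect_error(peak_amplitude(rec, variable = "nope"), "not recorded")
})

test_that("pre/post protocol places events at the signed interval", {
  cfg <- test_config()
  rec <- pre_post_protocol(cfg, interval = -30, t_pre = 100, t_tail = 100)
  # bAP at 70 ms: voltage peak precedes the glutamate pulse
  t_vpeak <- rec$time[which.max(rec$v)]
  expect_lt(abs(t_vpeak - 72), 5)
  expect_equal(max(rec$glu[rec$time < 99]), 0)
  expect_error(pre_post_protocol(cfg, interval = -300, t_pre = 100),
               "before time 0")
})

test_that("simulation configuration round-trips through YAML", {
  cfg <- spine_config(nmdar = nmdar_params(n_receptors = 12),
                      glu_amp = 0.5, dt = 0.004)
  f <- withr::local_tempfile(fileext = ".yaml")
  write_spine_config(cfg, f)
  back <- read_spine_config(f)
  expect_equal(back$nmdar$n_receptors, 12)
  expect_equal(back$glu$amp, 0.5)
  expect_equal(back$solver$dt, 0.004)
  expect_equal(back$pmca$i_max, cfg$pmca$i_max)
})

test_that("event trains round-trip through delimited text", {
  tr <- poisson_train(2, 20, seed = 3, kind = "post")
  f <- withr::local_tempfile(fileext = ".txt")
  write_event_train(tr, f)
  back <- read_event_train(f)
  expect_equal(back$time, tr$time)
  expect_identical(back$kind, tr$kind)
})
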