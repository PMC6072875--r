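test_that("Poisson trains have the right statistics and are reproducible", {
  tr <- poisson_train(2, 1000, seed = 123)
  isi <- diff(c(0, tr$time))
  # mean ISI within 3 standard errors of 500 ms
  expect_lt(abs(mean(isi) - 500), 3 * 500 / sqrt(1000))
  expect_identical(tr, poisson_train(2, 1000, seed = 123))
  expect_false(isTRUE(all.equal(tr$time,
                                poisson_train(2, 1000, seed = 124)$time)))
  # 10 Hz, 1000 events spans roughly 100 s
  tr10 <- poisson_train(10, 1000, seed = 5)
  expect_lt(abs(max(tr10$time) - 1e5), 3 * sqrt(1000) * 100)
  expect_error(poisson_train(0, 10, seed = 1), "positive")
  # generation leaves the caller's RNG stream untouched
  set.seed(99); a <- runif(1)
  set.seed(99); invisible(poisson_train(2, 10, seed = 1)); b <- runif(1)
  expect_identical(a, b)
})

test_that("event trains validate ordering and sign", {
  expect_error(event_train(c(3, 2, 5)), "increasing")
  expect_error(event_train(c(-1, 2)), "non-negative")
  tr <- event_train(c(1, 2, 3), "post")
  expect_identical(tr$kind, rep("post", 3))
})

test_that("Izhikevich neuron obeys its reset rule and rests without input", {
  p <- izhikevich_params()
  st <- izhikevich_step(29.99, 0, 100, p, dt = 1)  # forced over threshold
  expect_true(st$spiked)
  expect_equal(st$v, p$c)
  out <- izhikevich_run(numeric(), t_max = 500, p = p)
  expect_length(out$spikes, 0)
  expect_lt(max(abs(tail(out$trace$v, 100) - out$trace$v[length(out$trace$v)])), 5)
})

test_that("sustained suprathreshold current produces periodic spiking", {
  p <- izhikevich_params()
  out <- izhikevich_run(numeric(), t_max = 1000, p = p,
                        i_extra = function(t) rep(10, length(t)))
  expect_gt(length(out$spikes), 3)
  isi <- diff(out$spikes)
  late <- tail(isi, 3)
  expect_lt(max(late) - min(late), 0.05 * mean(late))
  # finer integration step gives the same spike count
  out2 <- izhikevich_run(numeric(), t_max = 1000, p = p, dt = 0.01,
                         i_extra = function(t) rep(10, length(t)))
  expect_lt(abs(length(out2$spikes) - length(out$spikes)), 2)
})

test_that("bAP waveform peaks at the attenuated amplitude and returns to rest", {
  w <- bap_waveform()
  t <- seq(0, 400, by = 0.01)
  v <- bap_voltage(t, w)
  expect_equal(max(v), w$v_rest + w$amp * w$atten, tolerance = 1e-5)
  expect_equal(v[length(v)], w$v_rest, tolerance = 1e-6)
  # attenuation scales the peak linearly
  w1 <- bap_waveform(atten = 1)
  expect_equal(max(bap_voltage(t, w1)) - w1$v_rest,
               (max(v) - w$v_rest) / 0.7, tolerance = 1e-6)
  expect_error(bap_voltage(-1, w), ">= 0")
})

test_that("spine voltage superposes bAPs over the resting potential", {
  w <- bap_waveform()
  t <- seq(0, 100, by = 0.1)
  v2 <- spine_voltage(t, c(20, 22), w)
  v_a <- spine_voltage(t, 20, w)
  v_b <- spine_voltage(t, 22, w)
  expect_equal(v2, v_a + v_b - w$v_rest, tolerance = 1e-12)
  expect_true(all(spine_voltage(t, numeric(), w) == w$v_rest))
})

test_that("backpropagation attenuation falls off with distance", {
  d <- c(0, 75, 150, 300, 400)
  a <- bap_attenuation(d)
  expect_true(all(diff(a) < 0))
  expect_equal(a[3], 0.7, tolerance = 0.01)
  expect_lt(a[4], 0.06)
})
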