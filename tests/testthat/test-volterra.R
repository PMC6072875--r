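test_that("discrete Laguerre basis is orthonormal over its window", {
  for (alpha in c(0.5, 0.8, 0.98)) {
    b <- laguerre_basis(alpha, n_basis = 4, memory = 2000)
    G <- crossprod(b$funs)
    expect_equal(G, diag(4), tolerance = 1e-6, ignore_attr = TRUE)
  }
  expect_error(laguerre_basis(1.2), "inside")
  expect_error(laguerre_basis(0), "inside")
})

test_that("recursive filtering equals direct convolution with the basis", {
  set.seed(21)
  b <- laguerre_basis(0.7, n_basis = 3, memory = 400)
  x <- rnorm(300)
  v_rec <- laguerre_filter(x, b)
  v_dir <- convolve_oracle(x, b$funs)
  expect_equal(v_rec, v_dir, tolerance = 1e-8)
  # unit impulse reproduces the basis functions themselves
  imp <- c(1, numeric(299))
  v_imp <- laguerre_filter(imp, b)
  expect_equal(v_imp, b$funs[1:300, ], tolerance = 1e-10)
  # zero input, zero output
  expect_true(all(laguerre_filter(numeric(100), b) == 0))
})

test_that("prediction equals the brute-force kernel-sum oracle", {
  set.seed(31)
  b1 <- laguerre_basis(0.6, n_basis = 3, memory = 50)
  b2 <- laguerre_basis(0.75, n_basis = 2, memory = 50)
  terms <- volterra_terms(3, 2, 3)
  # signals shorter than the memory window, so the truncated-convolution
  # oracle is exact
  for (rep in 1:3) {
    model <- make_volterra_model(rnorm(nrow(terms)), b1, b2)
    v <- rnorm(45)
    g <- rnorm(45)
    expect_equal(predict(model, v, g), volterra_oracle(model, v, g),
                 tolerance = 1e-8)
  }
})

test_that("zero inputs give the constant term; first order is homogeneous", {
  b <- laguerre_basis(0.7, n_basis = 2, memory = 60)
  terms <- volterra_terms(2, 2, 3)
  coef <- numeric(nrow(terms))
  coef[1] <- 4.2
  model <- make_volterra_model(coef, b, b)
  expect_equal(predict(model, numeric(80), numeric(80)), rep(4.2, 80))
  # only c1 terms nonzero: doubling inputs doubles (output - c0)
  coef[terms$kind == "c1_1"] <- c(0.5, -0.2)
  m1 <- make_volterra_model(coef, b, b)
  x <- rnorm(80)
  p1 <- predict(m1, x, numeric(80)) - 4.2
  p2 <- predict(m1, 2 * x, numeric(80)) - 4.2
  expect_equal(p2, 2 * p1, tolerance = 1e-10)
})

test_that("fitting recovers a known Volterra model exactly (noise-free)", {
  set.seed(41)
  b1 <- laguerre_basis(0.8, n_basis = 3, memory = 40)
  b2 <- laguerre_basis(0.85, n_basis = 3, memory = 40)
  terms <- volterra_terms(3, 3, 3)
  true_coef <- rnorm(nrow(terms), sd = 0.3)
  n <- 1200
  v <- rnorm(n)
  g <- rnorm(n)
  # generate the target with the exact standardization the fit will use, so
  # recovery is an identity up to numerical precision
  scaling <- list(mu_v = mean(v), sd_v = sd(v), mu_g = mean(g),
                  sd_g = sd(g))
  truth <- make_volterra_model(true_coef, b1, b2, scaling = scaling)
  train <- tibble::tibble(segment = 1, v = v, g = g,
                          ca = predict(truth, v, g))
  fit <- volterra_fit(train, b1, b2)
  expect_lt(fit$train_nrms, 1e-6)
  expect_equal(fit$coef, true_coef, tolerance = 1e-6)
  pv <- predict(fit, v, g)
  expect_equal(pv, train$ca, tolerance = 1e-6)
})

test_that("constant target yields c0 with vanishing kernels", {
  b <- laguerre_basis(0.8, n_basis = 2, memory = 30)
  set.seed(51)
  train <- tibble::tibble(segment = 1, v = rnorm(400), g = rnorm(400),
                          ca = 2.5)
  fit <- volterra_fit(train, b, b)
  expect_equal(fit$coef[1], 2.5, tolerance = 1e-8)
  expect_lt(max(abs(fit$coef[-1])), 1e-8)
})

test_that("training error never increases with basis order on fixed data", {
  set.seed(61)
  n <- 800
  v <- rnorm(n); g <- rnorm(n)
  ca <- 0.3 * stats::filter(v, 0.9, method = "recursive") +
    0.1 * (stats::filter(g, 0.8, method = "recursive"))^2
  train <- tibble::tibble(segment = 1, v = v, g = g, ca = as.numeric(ca))
  errs <- vapply(1:3, function(L) {
    volterra_fit(train, laguerre_basis(0.85, L, 30),
                 laguerre_basis(0.85, L, 30))$train_nrms
  }, numeric(1))
  expect_true(all(diff(errs) < 1e-8))
  err_o2 <- volterra_fit(train, laguerre_basis(0.85, 3, 30),
                         laguerre_basis(0.85, 3, 30), order = 2)$train_nrms
  expect_lte(errs[3], err_o2 + 1e-8)
})

test_that("normalized RMS matches its closed forms", {
  ref <- c(0, 1, 2, 5, 1)
  expect_equal(normalized_rms(ref, ref), 0)
  expect_equal(normalized_rms(ref + 0.5, ref), 100 * 0.5 / 5)
  expect_error(normalized_rms(rep(1, 3), rep(2, 3)), "constant")
  expect_error(normalized_rms(1:3, 1:4), "equal length")
})

test_that("decay optimization recovers the generating decay", {
  set.seed(71)
  b_true <- laguerre_basis(0.9, n_basis = 2, memory = 80)
  terms <- volterra_terms(2, 2, 2)
  coef <- rnorm(nrow(terms), sd = 0.5)
  truth <- make_volterra_model(coef, b_true, b_true, order = 2)
  n <- 1500
  v <- rnorm(n); g <- rnorm(n)
  train <- tibble::tibble(segment = 1, v = v, g = g,
                          ca = predict(truth, v, g))
  opt <- optimize_decay(train, init = c(0.85, 0.85), order = 2,
                        n_basis = c(2, 2), memory = 80, dt = 1,
                        grid = c(0.85, 0.9, 0.95), max_iter = 40)
  expect_lt(max(abs(opt$decays - 0.9)), 0.02)
  # accepted steps never increase the objective
  expect_lte(opt$nrms, min(opt$trace$nrms) + 1e-9)
})

test_that("flat objective returns the initial decays", {
  set.seed(81)
  train <- tibble::tibble(segment = 1, v = rnorm(300), g = rnorm(300),
                          ca = 0)
  opt <- optimize_decay(train, init = c(0.9, 0.9), order = 1,
                        n_basis = c(2, 2), memory = 30, grid = NULL,
                        max_iter = 5)
  expect_equal(opt$decays, c(0.9, 0.9))
})

test_that("a fitted model round-trips through its serialization file", {
  set.seed(91)
  b <- laguerre_basis(0.8, n_basis = 2, memory = 40)
  train <- tibble::tibble(segment = 1, v = rnorm(300), g = rnorm(300))
  train$ca <- 0.2 * train$v + 0.05 * train$g^2 + 1
  fit <- volterra_fit(train, b, b)
  f <- withr::local_tempfile(fileext = ".yaml")
  write_volterra_model(fit, f)
  back <- read_volterra_model(f)
  expect_equal(back$coef, fit$coef, tolerance = 1e-12)
  expect_equal(back$terms, fit$terms)
  expect_equal(back$scaling, fit$scaling, tolerance = 1e-12)
  x <- rnorm(100); y <- rnorm(100)
  expect_equal(predict(back, x, y), predict(fit, x, y), tolerance = 1e-10)
  expect_error(read_volterra_model(
    withr::local_tempfile(lines = "type: other", fileext = ".yaml")),
    "not a spinecal")
})

test_that("tidy and glance summarize a fitted model", {
  b <- laguerre_basis(0.8, n_basis = 2, memory = 30)
  set.seed(101)
  train <- tibble::tibble(segment = 1, v = rnorm(200), g = rnorm(200))
  train$ca <- train$v * 0.3
  fit <- volterra_fit(train, b, b)
  td <- tidy(fit)
  expect_identical(nrow(td), nrow(fit$terms))
  expect_true(all(c("kind", "estimate") %in% names(td)))
  gl <- glance(fit)
  expect_identical(nrow(gl), 1L)
  expect_equal(gl$n_coef, length(fit$coef))
})
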