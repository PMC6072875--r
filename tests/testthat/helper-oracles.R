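# Independent oracles used across the suite. These deliberately avoid the
# package's own fast paths: direct convolution instead of the Laguerre
# recursion, explicit nested kernel sums instead of the design matrix, and
# matrix exponentials / fine-step integration instead of the production
# integrator.

# discrete Laguerre basis by direct evaluation of the recursion's impulse
# response is what the package does; the oracle instead checks filtering by
# direct truncated convolution with a given basis matrix
convolve_oracle <- function(x, funs) {
  n <- length(x)
  M <- nrow(funs)
  out <- matrix(0, n, ncol(funs))
  for (t in seq_len(n)) {
    lags <- seq_len(min(t, M))
    out[t, ] <- drop(crossprod(funs[lags, , drop = FALSE],
                               x[t - lags + 1]))
  }
  out
}

# brute-force two-input Volterra evaluation: nested loops over every kernel
# index tuple, using triangular coefficient layouts exactly as documented
volterra_oracle <- function(model, v, g) {
  V1 <- convolve_oracle((v - model$scaling$mu_v) / model$scaling$sd_v,
                        model$basis_v$funs)
  V2 <- convolve_oracle((g - model$scaling$mu_g) / model$scaling$sd_g,
                        model$basis_g$funs)
  cf <- split(model$coef, model$terms$kind)
  tm <- split(model$terms, model$terms$kind)
  n <- length(v)
  out <- rep(cf$c0, n)
  add <- function(kind, f) {
    if (is.null(tm[[kind]])) return()
    t <- tm[[kind]]
    for (r in seq_len(nrow(t))) {
      out <<- out + cf[[kind]][r] * f(t$i1[r], t$i2[r], t$i3[r])
    }
  }
  add("c1_1", function(a, b, c) V1[, a])
  add("c1_2", function(a, b, c) V2[, a])
  add("c2s_1", function(a, b, c) V1[, a] * V1[, b])
  add("c2s_2", function(a, b, c) V2[, a] * V2[, b])
  add("c3s_1", function(a, b, c) V1[, a] * V1[, b] * V1[, c])
  add("c3s_2", function(a, b, c) V2[, a] * V2[, b] * V2[, c])
  add("c2x", function(a, b, c) V1[, a] * V2[, b])
  add("c3x1", function(a, b, c) V1[, a] * V1[, c] * V2[, b])
  add("c3x2", function(a, b, c) V1[, a] * V2[, b] * V2[, c])
  out
}

# build a volterra_model with given coefficients (bypassing fitting)
make_volterra_model <- function(coef, basis_v, basis_g, order = 3,
                                scaling = list(mu_v = 0, sd_v = 1,
                                               mu_g = 0, sd_g = 1)) {
  terms <- volterra_terms(basis_v$n_basis, basis_g$n_basis, order)
  stopifnot(length(coef) == nrow(terms))
  structure(list(coef = coef, terms = terms, basis_v = basis_v,
                 basis_g = basis_g, order = order, scaling = scaling,
                 train_nrms = NA_real_, condition = NA_real_,
                 rank = length(coef), n_train = 0L),
            class = "volterra_model")
}

# matrix-exponential reference for a piecewise-constant glutamate profile:
# occupancy after holding `glu` for `dur` ms
expm_occupancy <- function(occ0, glu, dur, scheme = nmdar_scheme()) {
  Q <- nmdar_rate_matrix(glu, scheme)
  drop(as.matrix(Matrix::expm(Q * dur)) %*% occ0)
}

# total calcium in spine-volume uM for a recorded state vector
state_total_ca <- function(y, config) {
  ns <- length(config$scheme$states)
  cb <- y[(7 + ns):(15 + ns)]
  sites <- sum(cb * (rep(0:2, each = 3) + rep(0:2, 3)))
  y[2] + y[1] * config$geometry$v_psd / config$geometry$v_spine +
    config$cam$h_c * y[5 + ns] + y[6 + ns] +
    config$calbindin$total * sites
}

# fast test configuration: coarser recording, everything else default
test_config <- function(...) spine_config(record_dt = 0.1, ...)
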