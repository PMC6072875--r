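#' Discrete orthonormal Laguerre basis
#'
#' The exponentially decaying orthonormal basis used to compress Volterra
#' kernels. A single decay parameter `alpha` controls how slowly the basis
#' functions die out; `n_basis` functions are kept and the kernels extend
#' over a memory window of `memory` taps at sampling interval `dt`.
#'
#' @param alpha Decay parameter, in (0, 1).
#' @param n_basis Number of basis functions (kernel order per dimension).
#' @param memory Memory window in taps (default 5000 taps = 5 s at 1 ms).
#' @param dt Sampling interval (ms).
#' @return An object of class `laguerre_basis`; its `funs` element is the
#'   `memory x n_basis` matrix of basis functions (orthonormal over the
#'   window as long as `alpha^memory` is negligible).
#' @export
laguerre_basis <- function(alpha, n_basis = 3, memory = 5000, dt = 1) {
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1) {
    abort("`alpha` must lie strictly inside (0, 1)")
  }
  if (n_basis < 1 || memory < n_basis) abort("need memory >= n_basis >= 1")
  impulse <- c(1, numeric(memory - 1))
  funs <- laguerre_filter_raw(impulse, alpha, n_basis)
  structure(list(alpha = alpha, n_basis = n_basis, memory = memory,
                 dt = dt, funs = funs),
            class = "laguerre_basis")
}

# recursive discrete-Laguerre filter bank; x is a plain numeric vector
laguerre_filter_raw <- function(x, alpha, n_basis) {
  sa <- sqrt(alpha)
  out <- matrix(0, length(x), n_basis)
  v <- stats::filter(sqrt(1 - alpha) * x, sa, method = "recursive")
  out[, 1] <- v
  if (n_basis > 1) {
    for (j in 2:n_basis) {
      prev <- out[, j - 1]
      drive <- sa * prev - c(0, prev[-length(prev)])
      out[, j] <- stats::filter(drive, sa, method = "recursive")
    }
  }
  out
}

#' Convolve an input trace with every Laguerre basis function
#'
#' Computes `v_j(t) = sum_tau b_j(tau) x(t - tau)` for all basis functions,
#' using the exact recursive form of the discrete Laguerre filter (equal to
#' direct truncated convolution up to the negligible tail beyond the memory
#' window).
#'
#' @param x Input trace, uniformly sampled at the basis sampling interval.
#' @param basis A [laguerre_basis()].
#' @return A `length(x) x n_basis` matrix of filtered traces.
#' @export
laguerre_filter <- function(x, basis) {
  if (!is.numeric(x)) abort("`x` must be a numeric trace")
  laguerre_filter_raw(as.numeric(x), basis$alpha, basis$n_basis)
}

#' Term table of the two-input Volterra series
#'
#' Enumerates every coefficient of the series: the 0th-order constant, each
#' input's 1st/2nd/3rd-order self-kernel terms in triangular
#' (symmetric-unique) layout, the 2nd-order cross kernel over both inputs,
#' and the two 3rd-order cross kernels (two factors from one input, one from
#' the other, triangular within the repeated input).
#'
#' @param L1,L2 Number of Laguerre basis functions for inputs 1 and 2.
#' @param order Highest kernel order (1-3).
#' @return A tibble with columns `term`, `kind` and basis indices
#'   `i1`, `i2`, `i3` (`NA` where unused). For `c3x1`, `i1 <= i3` index
#'   input 1 and `i2` indexes input 2; for `c3x2`, `i1` indexes input 1 and
#'   `i2 <= i3` index input 2.
#' @export
volterra_terms <- function(L1, L2, order = 3) {
  if (!order %in% 1:3) abort("`order` must be 1, 2 or 3")
  tri2 <- function(L) {
    idx <- which(lower.tri(diag(L), diag = TRUE), arr.ind = TRUE)
    idx[order(idx[, 2], idx[, 1]), , drop = FALSE]
  }
  tri3 <- function(L) {
    g <- expand.grid(a = seq_len(L), b = seq_len(L), c = seq_len(L))
    as.matrix(g[g$a <= g$b & g$b <= g$c, ])
  }
  rows <- list(tibble(kind = "c0", i1 = NA_integer_, i2 = NA_integer_,
                      i3 = NA_integer_))
  for (inp in 1:2) {
    L <- if (inp == 1) L1 else L2
    rows <- c(rows, list(tibble(kind = paste0("c1_", inp),
                                i1 = seq_len(L), i2 = NA_integer_,
                                i3 = NA_integer_)))
    if (order >= 2) {
      t2 <- tri2(L)
      rows <- c(rows, list(tibble(kind = paste0("c2s_", inp),
                                  i1 = as.integer(t2[, 2]),
                                  i2 = as.integer(t2[, 1]),
                                  i3 = NA_integer_)))
    }
    if (order >= 3) {
      t3 <- tri3(L)
      rows <- c(rows, list(tibble(kind = paste0("c3s_", inp),
                                  i1 = as.integer(t3[, 1]),
                                  i2 = as.integer(t3[, 2]),
                                  i3 = as.integer(t3[, 3]))))
    }
  }
  if (order >= 2) {
    g <- expand.grid(i1 = seq_len(L1), i2 = seq_len(L2))
    rows <- c(rows, list(tibble(kind = "c2x", i1 = g$i1, i2 = g$i2,
                                i3 = NA_integer_)))
  }
  if (order >= 3) {
    t2a <- tri2(L1)
    g1 <- expand.grid(p = seq_len(nrow(t2a)), k2 = seq_len(L2))
    rows <- c(rows, list(tibble(kind = "c3x1",
                                i1 = as.integer(t2a[g1$p, 2]),
                                i2 = as.integer(g1$k2),
                                i3 = as.integer(t2a[g1$p, 1]))))
    t2b <- tri2(L2)
    g2 <- expand.grid(k1 = seq_len(L1), p = seq_len(nrow(t2b)))
    rows <- c(rows, list(tibble(kind = "c3x2",
                                i1 = as.integer(g2$k1),
                                i2 = as.integer(t2b[g2$p, 2]),
                                i3 = as.integer(t2b[g2$p, 1]))))
  }
  out <- dplyr::bind_rows(rows)
  out$term <- seq_len(nrow(out))
  dplyr::relocate(out, "term")
}

# design matrix of all basis-product regressors for filtered inputs V1, V2
volterra_design <- function(V1, V2, terms) {
  n <- nrow(V1)
  X <- matrix(0, n, nrow(terms))
  for (r in seq_len(nrow(terms))) {
    X[, r] <- switch(
      terms$kind[r],
      c0 = rep(1, n),
      c1_1 = V1[, terms$i1[r]],
      c1_2 = V2[, terms$i1[r]],
      c2s_1 = V1[, terms$i1[r]] * V1[, terms$i2[r]],
      c2s_2 = V2[, terms$i1[r]] * V2[, terms$i2[r]],
      c3s_1 = V1[, terms$i1[r]] * V1[, terms$i2[r]] * V1[, terms$i3[r]],
      c3s_2 = V2[, terms$i1[r]] * V2[, terms$i2[r]] * V2[, terms$i3[r]],
      c2x = V1[, terms$i1[r]] * V2[, terms$i2[r]],
      c3x1 = V1[, terms$i1[r]] * V1[, terms$i3[r]] * V2[, terms$i2[r]],
      c3x2 = V1[, terms$i1[r]] * V2[, terms$i2[r]] * V2[, terms$i3[r]],
      abort("unknown term kind"))
  }
  X
}

# Moore-Penrose pseudoinverse least squares; returns coefficients and the
# design condition number
pinv_solve <- function(X, y, tol = 1e-10) {
  sv <- svd(X)
  d <- sv$d
  keep <- d > tol * d[1]
  coef <- sv$v[, keep, drop = FALSE] %*%
    ((crossprod(sv$u[, keep, drop = FALSE], y)) / d[keep])
  list(coef = drop(coef), condition = d[1] / min(d[d > 0]),
       rank = sum(keep))
}

#' Range-normalized root-mean-square difference
#'
#' RMS difference between a predicted and a reference trace, normalized to
#' the reference's max-minus-min range, in percent. The accuracy metric used
#' for every surrogate/baseline comparison in the package.
#'
#' @param pred Predicted trace.
#' @param ref Reference trace (same length); must not be constant.
#' @return Percent NRMS.
#' @export
normalized_rms <- function(pred, ref) {
  if (length(pred) != length(ref)) abort("traces must have equal length")
  rng <- max(ref) - min(ref)
  if (rng <= 0) abort("reference trace is constant; NRMS undefined")
  100 * sqrt(mean((pred - ref)^2)) / rng
}

#' Fit the two-input third-order Volterra model
#'
#' Estimates all kernel coefficients by pseudoinverse least squares on the
#' Laguerre-filtered inputs, jointly over every training segment. Inputs are
#' standardized (z-scored on pooled training statistics, which are stored in
#' the model) before filtering; the first memory-window of each segment is
#' excluded from the loss so only fully-initialized filter states are fit.
#'
#' @param train Training set: a tibble with columns `segment`, `v`
#'   (postsynaptic potential, mV), `g` (total NMDAr conductance, pS) and
#'   `ca` (spine calcium, uM), uniformly sampled at the basis `dt`. See
#'   [make_io_training_set()].
#' @param basis_v,basis_g [laguerre_basis()] objects for the two inputs.
#' @param order Highest kernel order (default 3).
#' @return An object of class `volterra_model`: coefficients, term table,
#'   bases, input scaling, training NRMS (percent) and design condition
#'   number.
#' @export
volterra_fit <- function(train, basis_v, basis_g, order = 3) {
  need <- c("segment", "v", "g", "ca")
  if (!all(need %in% names(train))) {
    abort("`train` must have columns segment, v, g, ca")
  }
  scaling <- list(mu_v = mean(train$v), sd_v = sd(train$v),
                  mu_g = mean(train$g), sd_g = sd(train$g))
  if (scaling$sd_v == 0) scaling$sd_v <- 1
  if (scaling$sd_g == 0) scaling$sd_g <- 1
  terms <- volterra_terms(basis_v$n_basis, basis_g$n_basis, order)
  segs <- split(train, train$segment)
  Xs <- vector("list", length(segs))
  ys <- vector("list", length(segs))
  for (i in seq_along(segs)) {
    s <- segs[[i]]
    if (nrow(s) <= basis_v$memory) {
      abort("training segments must be longer than the memory window")
    }
    V1 <- laguerre_filter((s$v - scaling$mu_v) / scaling$sd_v, basis_v)
    V2 <- laguerre_filter((s$g - scaling$mu_g) / scaling$sd_g, basis_g)
    keep <- seq_len(nrow(s)) > basis_v$memory
    Xs[[i]] <- volterra_design(V1[keep, , drop = FALSE],
                               V2[keep, , drop = FALSE], terms)
    ys[[i]] <- s$ca[keep]
  }
  X <- do.call(rbind, Xs)
  y <- do.call(c, ys)
  sol <- pinv_solve(X, y)
  pred <- drop(X %*% sol$coef)
  # a constant target has no range to normalize by; report the raw RMS then
  nrms <- if (max(y) > min(y)) normalized_rms(pred, y)
    else 100 * sqrt(mean((pred - y)^2))
  structure(
    list(coef = sol$coef, terms = terms, basis_v = basis_v,
         basis_g = basis_g, order = order, scaling = scaling,
         train_nrms = nrms, condition = sol$condition,
         rank = sol$rank, n_train = length(y)),
    class = "volterra_model")
}

#' Predict spine calcium from a fitted Volterra model
#'
#' @param object A `volterra_model`.
#' @param v Postsynaptic potential trace (mV), sampled at the model `dt`.
#' @param g Total NMDAr conductance trace (pS), same length.
#' @param ... Unused.
#' @return Predicted spine calcium trace (uM). With both inputs at the
#'   training mean the prediction is the constant 0th-order coefficient.
#' @export
predict.volterra_model <- function(object, v, g, ...) {
  if (length(v) != length(g)) abort("input traces must have equal length")
  V1 <- laguerre_filter((v - object$scaling$mu_v) / object$scaling$sd_v,
                        object$basis_v)
  V2 <- laguerre_filter((g - object$scaling$mu_g) / object$scaling$sd_g,
                        object$basis_g)
  drop(volterra_design(V1, V2, object$terms) %*% object$coef)
}

#' @export
print.volterra_model <- function(x, ...) {
  cat("<volterra_model> two-input Volterra series, order", x$order, "\n")
  cat("  L1 =", x$basis_v$n_basis, "(V), L2 =", x$basis_g$n_basis,
      "(g_NMDA);", length(x$coef), "coefficients\n")
  cat("  decays: alpha_v =", round(x$basis_v$alpha, 4),
      ", alpha_g =", round(x$basis_g$alpha, 4), "\n")
  cat("  training NRMS:", round(x$train_nrms, 3), "%\n")
  invisible(x)
}

#' @rdname volterra_tidiers
#' @method tidy volterra_model
#' @export
tidy.volterra_model <- function(x, ...) {
  dplyr::mutate(x$terms, estimate = x$coef)
}

#' Broom-style summaries of a fitted Volterra model
#'
#' `tidy()` returns one row per kernel coefficient with its term kind and
#' basis indices; `glance()` returns a one-row model summary.
#'
#' @param x A `volterra_model`.
#' @param ... Unused.
#' @return A tibble.
#' @name volterra_tidiers
#' @method glance volterra_model
#' @export
glance.volterra_model <- function(x, ...) {
  tibble(order = x$order, n_coef = length(x$coef),
         alpha_v = x$basis_v$alpha, alpha_g = x$basis_g$alpha,
         memory = x$basis_v$memory, dt = x$basis_v$dt,
         train_nrms = x$train_nrms, condition = x$condition,
         rank = x$rank, n_train = x$n_train)
}

#' Optimize the Laguerre decay parameters
#'
#' Minimizes the training NRMS over the two decay parameters by
#' coarse grid seeding followed by projected gradient descent with central
#' numerical gradients (fixed step on the decays, stopping when the
#' objective improves by less than `tol` or after `max_iter` iterations).
#' Decays are clipped to stay inside (0, 1).
#'
#' @inheritParams volterra_fit
#' @param init Initial decays `c(alpha_v, alpha_g)`.
#' @param grid Optional vector of decay values whose outer product seeds the
#'   descent (set `NULL` to start from `init` directly).
#' @param step Gradient-descent step size on the decays.
#' @param tol Absolute objective-improvement stopping tolerance (percent
#'   NRMS).
#' @param max_iter Maximum descent iterations.
#' @return A list with `decays`, the refit `model`, the achieved `nrms`, and
#'   the evaluation `trace` tibble.
#' @export
optimize_decay <- function(train, init = c(0.98, 0.98), order = 3,
                           n_basis = c(3, 3), memory = 5000, dt = 1,
                           grid = c(0.95, 0.98, 0.995), step = 1e-3,
                           tol = 1e-4, max_iter = 200) {
  if (any(init <= 0) || any(init >= 1)) abort("`init` decays must be in (0,1)")
  evals <- list()
  objective <- function(a) {
    m <- volterra_fit(train,
                      laguerre_basis(a[1], n_basis[1], memory, dt),
                      laguerre_basis(a[2], n_basis[2], memory, dt), order)
    evals[[length(evals) + 1]] <<- c(a, m$train_nrms)
    m$train_nrms
  }
  clip <- function(a) pmin(pmax(a, 0.5), 0.9995)
  best <- init
  best_f <- objective(init)
  if (!is.null(grid)) {
    for (a1 in grid) for (a2 in grid) {
      if (a1 == init[1] && a2 == init[2]) next
      f <- objective(c(a1, a2))
      if (f < best_f - 1e-12) { best <- c(a1, a2); best_f <- f }
    }
  }
  a <- best
  f <- best_f
  h <- 1e-3
  for (it in seq_len(max_iter)) {
    gr <- c(
      (objective(clip(a + c(h, 0))) - objective(clip(a - c(h, 0)))) / (2 * h),
      (objective(clip(a + c(0, h))) - objective(clip(a - c(0, h)))) / (2 * h))
    gn <- sqrt(sum(gr^2))
    if (gn == 0) break
    cand <- clip(a - step * gr / gn)
    f_new <- objective(cand)
    if (f_new < f) {
      improved <- f - f_new
      a <- cand
      f <- f_new
      if (improved < tol) break
    } else break
  }
  trace <- do.call(rbind, evals)
  model <- volterra_fit(train,
                        laguerre_basis(a[1], n_basis[1], memory, dt),
                        laguerre_basis(a[2], n_basis[2], memory, dt), order)
  list(decays = a, model = model, nrms = model$train_nrms,
       trace = tibble(alpha_v = trace[, 1], alpha_g = trace[, 2],
                      nrms = trace[, 3]))
}

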