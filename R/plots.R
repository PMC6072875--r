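#' Plot a simulation record
#'
#' Stacked traces of spine/PSD calcium, membrane potential and total NMDAr
#' conductance against time.
#'
#' @param object A `spine_sim` tibble from [run_simulation()].
#' @param vars Recorded columns to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.spine_sim <- function(object,
                               vars = c("ca_spine", "ca_psd", "v",
                                        "g_nmda"), ...) {
  vars <- intersect(vars, names(object))
  long <- tidyr::pivot_longer(object[, c("time", vars)],
                              dplyr::all_of(vars),
                              names_to = "variable", values_to = "value")
  long$variable <- factor(long$variable, levels = vars)
  ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$variable),
                        scales = "free_y") +
    ggplot2::labs(x = "time (ms)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an interval-sweep result
#'
#' Peak spine calcium against the signed pre/post interval, the
#' spike-timing curve of the model.
#'
#' @param sweep Tibble from [interval_sweep()].
#' @return A ggplot object.
#' @export
plot_interval_sweep <- function(sweep) {
  ggplot2::ggplot(sweep, ggplot2::aes(.data$interval, .data$peak)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::labs(x = "pre-to-post interval (ms)",
                  y = "peak spine calcium (uM)") +
    ggplot2::theme_minimal()
}

#' Plot fitted Laguerre-Volterra first-order kernels
#'
#' Reconstructs and draws the first-order kernel of each input,
#' `k1(tau) = sum_j c1(j) b_j(tau)`.
#'
#' @param object A `volterra_model`.
#' @param max_lag Maximum lag to draw (taps); defaults to a tenth of the
#'   memory window.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.volterra_model <- function(object, max_lag = NULL, ...) {
  max_lag <- max_lag %||% (object$basis_v$memory %/% 10)
  k1 <- function(basis, kind) {
    idx <- object$terms$kind == kind
    drop(basis$funs[seq_len(max_lag), , drop = FALSE] %*%
           object$coef[idx])
  }
  d <- dplyr::bind_rows(
    tibble(input = "postsynaptic potential",
           lag = (seq_len(max_lag) - 1) * object$basis_v$dt,
           kernel = k1(object$basis_v, "c1_1")),
    tibble(input = "NMDAr conductance",
           lag = (seq_len(max_lag) - 1) * object$basis_g$dt,
           kernel = k1(object$basis_g, "c1_2")))
  ggplot2::ggplot(d, ggplot2::aes(.data$lag, .data$kernel)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$input), scales = "free_y") +
    ggplot2::labs(x = "lag (ms)", y = "first-order kernel") +
    ggplot2::theme_minimal()
}

#' Plot surrogate validation traces
#'
#' Mechanistic versus surrogate (and, when present, linear-baseline)
#' calcium traces for each validation rate.
#'
#' @param object An `io_report` from [run_io_protocol()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.io_report <- function(object, ...) {
  tr <- object$traces
  vars <- intersect(c("ca_mech", "ca_io", "ca_linear"), names(tr))
  long <- tidyr::pivot_longer(tr, dplyr::all_of(vars),
                              names_to = "model", values_to = "ca")
  ggplot2::ggplot(long,
                  ggplot2::aes(.data$time / 1000, .data$ca,
                               colour = .data$model)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$rate), scales = "free") +
    ggplot2::labs(x = "time (s)", y = "spine calcium (uM)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
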