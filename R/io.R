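#' Read and write event trains as delimited text
#'
#' Two-column tab-separated format: `time_ms`, `kind` (`pre`/`post`).
#'
#' @param x An [event_train()] (or a tibble with `time` and `kind`).
#' @param file Path.
#' @return `read_event_train()` returns an `event_train` tibble (single
#'   kind) or a plain tibble when the file mixes kinds.
#' @export
write_event_train <- function(x, file) {
  utils::write.table(data.frame(time_ms = x$time, kind = x$kind), file,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_event_train
#' @export
read_event_train <- function(file) {
  d <- utils::read.delim(file, stringsAsFactors = FALSE)
  if (!all(c("time_ms", "kind") %in% names(d))) {
    abort("event-train files need columns time_ms and kind")
  }
  kinds <- unique(d$kind)
  if (length(kinds) == 1) event_train(d$time_ms, kinds)
  else tibble(time = d$time_ms, kind = d$kind)
}

#' Write / read a simulation configuration as YAML
#'
#' Serializes every parameter block of a [spine_config()] (the NMDAr kinetic
#' scheme itself stays in its own edge-list file and is referenced by the
#' configuration). Reading merges the stored values over the package
#' defaults, so partial files work as overrides.
#'
#' @param config A [spine_config()].
#' @param file Path.
#' @export
write_spine_config <- function(config, file) {
  drop_class <- function(x) if (is.list(x)) lapply(unclass(x), drop_class)
    else x
  blocks <- config[setdiff(names(config), "scheme")]
  yaml::write_yaml(drop_class(blocks), file)
  invisible(file)
}

#' @rdname write_spine_config
#' @export
read_spine_config <- function(file) {
  stored <- yaml::read_yaml(file)
  base <- spine_config()
  for (nm in intersect(names(stored), names(base))) {
    if (is.list(base[[nm]])) {
      base[[nm]] <- modifyList(base[[nm]], stored[[nm]])
    } else {
      base[[nm]] <- stored[[nm]]
    }
  }
  base
}

#' Serialize a fitted Volterra model
#'
#' Writes a single self-describing YAML file holding the decays, orders,
#' memory window, sampling interval, input scaling and every kernel
#' coefficient with its term indices; `read_volterra_model()` reconstructs
#' an identical model (round-trip exact to the printed precision, 17
#' significant digits).
#'
#' @param model A `volterra_model`.
#' @param file Path.
#' @export
write_volterra_model <- function(model, file) {
  obj <- list(
    type = "spinecal_volterra_model", version = 1L,
    order = model$order,
    basis_v = list(alpha = model$basis_v$alpha,
                   n_basis = model$basis_v$n_basis,
                   memory = model$basis_v$memory, dt = model$basis_v$dt),
    basis_g = list(alpha = model$basis_g$alpha,
                   n_basis = model$basis_g$n_basis,
                   memory = model$basis_g$memory, dt = model$basis_g$dt),
    scaling = model$scaling,
    train_nrms = model$train_nrms, condition = model$condition,
    rank = model$rank, n_train = model$n_train,
    terms = list(kind = model$terms$kind, i1 = model$terms$i1,
                 i2 = model$terms$i2, i3 = model$terms$i3),
    coef = model$coef)
  yaml::write_yaml(obj, file, precision = 17)
  invisible(file)
}

#' @rdname write_volterra_model
#' @export
read_volterra_model <- function(file) {
  obj <- yaml::read_yaml(file)
  if (!identical(obj$type, "spinecal_volterra_model")) {
    abort("not a spinecal Volterra model file")
  }
  as_int_na <- function(x) {
    vapply(x, function(v) if (is.null(v) || is.na(v)) NA_integer_
           else as.integer(v), integer(1))
  }
  terms <- tibble(term = seq_along(obj$terms$kind),
                  kind = unlist(obj$terms$kind),
                  i1 = as_int_na(obj$terms$i1),
                  i2 = as_int_na(obj$terms$i2),
                  i3 = as_int_na(obj$terms$i3))
  structure(
    list(coef = as.numeric(obj$coef), terms = terms,
         basis_v = laguerre_basis(obj$basis_v$alpha, obj$basis_v$n_basis,
                                  obj$basis_v$memory, obj$basis_v$dt),
         basis_g = laguerre_basis(obj$basis_g$alpha, obj$basis_g$n_basis,
                                  obj$basis_g$memory, obj$basis_g$dt),
         order = obj$order, scaling = obj$scaling,
         train_nrms = obj$train_nrms, condition = obj$condition,
         rank = obj$rank, n_train = obj$n_train),
    class = "volterra_model")
}
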