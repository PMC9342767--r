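# Layer descriptors and model specs. A ModelSpec is a plain, declarative
# layer table: enough to count trainable parameters exactly, to initialize a
# weight bundle, and (for the layer kinds the forward engine supports) to run
# the network. Layers with `in_forward = FALSE` are retained in the parameter
# bundle (and counted) but bypassed by the forward pass -- this models a base
# network whose original classifier rides along in the transmitted weights
# even though a composed head taps the features below it.

layer_conv2d <- function(name, in_ch, out_ch, kernel, stride = 1L, pad = 0L,
                         bias = TRUE, in_forward = TRUE) {
  list(kind = "conv2d", name = name, in_ch = in_ch, out_ch = out_ch,
       kernel = kernel, stride = stride, pad = pad, bias = bias,
       in_forward = in_forward)
}

layer_dense <- function(name, d_in, d_out, bias = TRUE, in_forward = TRUE) {
  list(kind = "dense", name = name, d_in = d_in, d_out = d_out, bias = bias,
       in_forward = in_forward)
}

layer_batch_norm <- function(name, ch, in_forward = TRUE) {
  list(kind = "batch_norm", name = name, ch = ch, in_forward = in_forward)
}

layer_relu       <- function() list(kind = "relu", in_forward = TRUE)
layer_sigmoid    <- function() list(kind = "sigmoid", in_forward = TRUE)
layer_dropout    <- function(p = 0.5) list(kind = "dropout", p = p, in_forward = TRUE)
layer_flatten    <- function() list(kind = "flatten", in_forward = TRUE)
layer_gap        <- function() list(kind = "global_avg_pool", in_forward = TRUE)
layer_series_max <- function() list(kind = "series_max", in_forward = TRUE)
layer_max_pool   <- function(kernel, stride = kernel, pad = 0L)
  list(kind = "max_pool", kernel = kernel, stride = stride, pad = pad, in_forward = TRUE)
layer_avg_pool   <- function(kernel, stride = kernel)
  list(kind = "avg_pool", kernel = kernel, stride = stride, in_forward = TRUE)

#' Construct a model specification
#'
#' A model spec is an ordered layer table plus declared input and output
#' shapes. The trainable-parameter count is computable from the spec alone.
#'
#' @param layers list of layer descriptors.
#' @param input_dim integer vector, e.g. `c(3, 224, 224)` (channels, H, W).
#' @param output_dim integer vector (a scalar for a feature/logit vector).
#' @param name model name.
#' @return object of class `model_spec`.
#' @export
model_spec <- function(layers, input_dim, output_dim, name = "model") {
  structure(list(layers = layers, input_dim = as.integer(input_dim),
                 output_dim = as.integer(output_dim), name = name),
            class = "model_spec")
}

#' Compose a base model with a head
#'
#' Vertical model composition: a base mapping R^a -> R^b composed with a head
#' mapping R^b -> R^c gives a model R^a -> R^c. The head's declared input
#' shape must equal the base's output shape. A `NULL` head returns a
#' composition that is semantically the base model unchanged.
#'
#' @param base a `model_spec`.
#' @param head a `model_spec` or `NULL`.
#' @return object of class `composed_model_spec`.
#' @export
compose <- function(base, head = NULL) {
  stopifnot(inherits(base, "model_spec"))
  if (!is.null(head)) {
    stopifnot(inherits(head, "model_spec"))
    if (!identical(base$output_dim, head$input_dim))
      abort_composition(sprintf(
        "base output shape [%s] does not match head input shape [%s]",
        paste(base$output_dim, collapse = "x"),
        paste(head$input_dim, collapse = "x")))
  }
  out_dim <- if (is.null(head)) base$output_dim else head$output_dim
  structure(list(base = base, head = head, input_dim = base$input_dim,
                 output_dim = out_dim,
                 name = if (is.null(head)) base$name
                        else paste0(base$name, "∘", head$name)),
            class = "composed_model_spec")
}

layer_param_shapes <- function(layer) {
  switch(layer$kind,
    conv2d = {
      s <- list(weight = c(layer$out_ch, layer$in_ch, layer$kernel, layer$kernel))
      if (layer$bias) s$bias <- layer$out_ch
      names(s) <- paste0(layer$name, ".", names(s))
      s
    },
    dense = {
      s <- list(weight = c(layer$d_out, layer$d_in))
      if (layer$bias) s$bias <- layer$d_out
      names(s) <- paste0(layer$name, ".", names(s))
      s
    },
    batch_norm = {
      s <- list(weight = layer$ch, bias = layer$ch)
      names(s) <- paste0(layer$name, ".", names(s))
      s
    },
    list()
  )
}

spec_param_shapes <- function(spec) {
  if (inherits(spec, "composed_model_spec")) {
    shapes <- spec_param_shapes(spec$base)
    if (!is.null(spec$head)) shapes <- c(shapes, spec_param_shapes(spec$head))
    return(shapes)
  }
  out <- list()
  for (layer in spec$layers) out <- c(out, layer_param_shapes(layer))
  out
}

#' Count trainable parameters
#'
#' Exact count of trainable scalars (weights and biases of every retained
#' layer, whether or not the layer is on the forward path) of a model spec or
#' a composed spec.
#'
#' @param spec a `model_spec` or `composed_model_spec`.
#' @return numeric count (exact integer value).
#' @export
count_trainable <- function(spec) {
  sum(vapply(spec_param_shapes(spec), prod, 1.0))
}

#' Per-layer parameter table
#'
#' @param spec a `model_spec` or `composed_model_spec`.
#' @return data.frame with one row per parameter tensor: name, shape, count.
#' @export
param_table <- function(spec) {
  shapes <- spec_param_shapes(spec)
  data.frame(name = names(shapes),
             shape = vapply(shapes, function(s) paste(s, collapse = "x"), ""),
             count = vapply(shapes, prod, 1.0),
             row.names = NULL)
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> %s: [%s] -> [%s], %s trainable parameters\n",
              x$name, paste(x$input_dim, collapse = "x"),
              paste(x$output_dim, collapse = "x"),
              format(count_trainable(x), big.mark = ",")))
  invisible(x)
}

#' @export
print.composed_model_spec <- function(x, ...) {
  cat(sprintf("<composed_model_spec> %s: [%s] -> [%s], %s trainable parameters\n",
              x$name, paste(x$input_dim, collapse = "x"),
              paste(x$output_dim, collapse = "x"),
              format(count_trainable(x), big.mark = ",")))
  invisible(x)
}
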