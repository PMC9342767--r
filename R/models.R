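# Reference architectures. Two full-scale specs whose exact trainable
# parameter counts are contractual (the AlexNet-based MRI-series classifier
# and the DenseNet-121 chest-radiograph classifier), plus a tiny CNN family
# with the same base/head composition contract that trains in seconds on a
# CPU for protocol simulations.

#' AlexNet base model (feature extractor with retained classifier)
#'
#' Standard 1000-class AlexNet. For series classification only the
#' convolutional feature extractor is on the forward path (input
#' 3 x 224 x 224 -> features 256 x 6 x 6); the original classifier
#' (9216 -> 4096 -> 4096 -> 1000) is retained in the weight bundle -- and in
#' the parameter count -- but bypassed, so that the transmitted base weights
#' are the complete pretrained model.
#'
#' @return a `model_spec` with output shape `c(256, 6, 6)`.
#' @export
build_alexnet_base <- function() {
  layers <- list(
    layer_conv2d("base/features.conv1", 3L, 64L, 11L, stride = 4L, pad = 2L),
    layer_relu(), layer_max_pool(3L, 2L),
    layer_conv2d("base/features.conv2", 64L, 192L, 5L, pad = 2L),
    layer_relu(), layer_max_pool(3L, 2L),
    layer_conv2d("base/features.conv3", 192L, 384L, 3L, pad = 1L),
    layer_relu(),
    layer_conv2d("base/features.conv4", 384L, 256L, 3L, pad = 1L),
    layer_relu(),
    layer_conv2d("base/features.conv5", 256L, 256L, 3L, pad = 1L),
    layer_relu(), layer_max_pool(3L, 2L),
    # original ImageNet classifier: stored and counted, not on the series path
    layer_dense("base/classifier.fc1", 9216L, 4096L, in_forward = FALSE),
    layer_dense("base/classifier.fc2", 4096L, 4096L, in_forward = FALSE),
    layer_dense("base/classifier.fc3", 4096L, 1000L, in_forward = FALSE)
  )
  model_spec(layers, input_dim = c(3L, 224L, 224L),
             output_dim = c(256L, 6L, 6L), name = "alexnet")
}

#' MRI-series composed model
#'
#' An exam is a series of s images (s x 3 x 224 x 224). Each slice passes
#' through the AlexNet feature extractor to a 256 x 6 x 6 tensor; global
#' average pooling reduces each slice to 256 features, a max over the series
#' axis reduces s x 256 to 256, and a fully connected 256 -> 1 layer emits
#' one logit. All 61,101,097 parameters of the base (classifier included)
#' plus the 257-parameter head are trainable.
#'
#' @return a `composed_model_spec`.
#' @export
build_mri_model <- function() {
  head <- model_spec(
    list(layer_gap(), layer_series_max(), layer_dense("head/fc", 256L, 1L)),
    input_dim = c(256L, 6L, 6L), output_dim = 1L, name = "series-head")
  compose(build_alexnet_base(), head)
}

#' DenseNet-121 base (feature extractor through global pooling)
#'
#' Standard DenseNet-121: initial 7x7 conv (64 features), dense blocks of
#' 6/12/24/16 layers with growth rate 32 and bottleneck width 4x32, batch
#' norm throughout, transitions halving the channel count, final batch norm
#' and global average pooling to a 1024-vector. Convolutions are bias-free
#' (the batch norms carry the offsets). The original 1024 -> 1000 ImageNet
#' classifier is *not* part of this base: composition replaces it.
#'
#' @return a `model_spec` with output shape 1024.
#' @export
build_densenet121_base <- function() {
  layers <- list(
    layer_conv2d("base/conv0", 3L, 64L, 7L, stride = 2L, pad = 3L, bias = FALSE),
    layer_batch_norm("base/norm0", 64L),
    layer_relu(), layer_max_pool(3L, 2L, pad = 1L)
  )
  growth <- 32L; bn_width <- 4L * growth
  ch <- 64L
  blocks <- c(6L, 12L, 24L, 16L)
  for (b in seq_along(blocks)) {
    for (l in seq_len(blocks[b])) {
      pre <- sprintf("base/block%d.layer%d", b, l)
      layers <- c(layers, list(
        layer_batch_norm(paste0(pre, ".norm1"), ch),
        layer_relu(),
        layer_conv2d(paste0(pre, ".conv1"), ch, bn_width, 1L, bias = FALSE),
        layer_batch_norm(paste0(pre, ".norm2"), bn_width),
        layer_relu(),
        layer_conv2d(paste0(pre, ".conv2"), bn_width, growth, 3L, pad = 1L,
                     bias = FALSE)
      ))
      ch <- ch + growth   # dense connectivity: outputs concatenate
    }
    if (b < length(blocks)) {
      pre <- sprintf("base/transition%d", b)
      layers <- c(layers, list(
        layer_batch_norm(paste0(pre, ".norm"), ch),
        layer_relu(),
        layer_conv2d(paste0(pre, ".conv"), ch, ch %/% 2L, 1L, bias = FALSE),
        layer_avg_pool(2L, 2L)
      ))
      ch <- ch %/% 2L
    }
  }
  layers <- c(layers, list(layer_batch_norm("base/norm_final", ch),
                           layer_relu(), layer_gap()))
  model_spec(layers, input_dim = c(3L, 224L, 224L), output_dim = ch,
             name = "densenet121")
}

#' Chest-radiograph composed model
#'
#' DenseNet-121 with its 1000-node ImageNet classifier replaced by a 14-node
#' fully connected layer with sigmoid nonlinearity, one output probability
#' per thoracic-disease label. 6,968,206 trainable parameters.
#'
#' @return a `composed_model_spec`.
#' @export
build_xray_model <- function() {
  head <- model_spec(
    list(layer_dense("head/classifier", 1024L, 14L), layer_sigmoid()),
    input_dim = 1024L, output_dim = 14L, name = "xray-head")
  compose(build_densenet121_base(), head)
}

#' Tiny CNN family for desk-scale simulation
#'
#' A two-convolution base (3x3 kernels, 2x2 max pools, global average pool)
#' and a linear head obeying the same base/head composition contract as the
#' full-scale models. With `pretrain_classes` set, the base also carries a
#' classifier used by the vertical trainer for supervised pretraining; like
#' the AlexNet classifier it stays in the bundle but is bypassed once a
#' series/multi-label head is attached downstream.
#'
#' @param input_shape `c(channels, H, W)`; H and W must be multiples of 4.
#' @param base_out number of base feature channels (head input width).
#' @param head_out number of head outputs (1 for binary, L for multi-label).
#' @param series if `TRUE` the head reduces a series of slices by a max over
#'   the series axis before the linear layer (exam-level classification).
#' @param pretrain_classes optional number of classes for the ride-along base
#'   classifier.
#' @return a `composed_model_spec`.
#' @export
build_tiny_model <- function(input_shape = c(1L, 32L, 32L), base_out = 16L,
                             head_out = 1L, series = TRUE,
                             pretrain_classes = NULL) {
  base <- tiny_base_spec(input_shape, base_out, pretrain_classes,
                         classifier_active = FALSE)
  head_layers <- if (series)
    list(layer_series_max(), layer_dense("head/fc", base_out, head_out))
  else
    list(layer_dense("head/fc", base_out, head_out))
  head <- model_spec(head_layers, input_dim = base_out, output_dim = head_out,
                     name = "tiny-head")
  compose(base, head)
}

tiny_base_spec <- function(input_shape, base_out, pretrain_classes,
                           classifier_active) {
  ch <- input_shape[1]
  layers <- list(
    layer_conv2d("base/conv1", ch, 8L, 3L, pad = 1L),
    layer_relu(), layer_max_pool(2L, 2L),
    layer_conv2d("base/conv2", 8L, base_out, 3L, pad = 1L),
    layer_relu(), layer_max_pool(2L, 2L),
    layer_gap()
  )
  if (!is.null(pretrain_classes))
    layers <- c(layers, list(
      layer_dense("base/classifier", base_out, as.integer(pretrain_classes),
                  in_forward = classifier_active)))
  model_spec(layers, input_dim = input_shape, output_dim = base_out,
             name = "tiny")
}

#' Tiny vertical-pretraining model
#'
#' The tiny base with its multi-class classifier on the forward path and a
#' null head: the model the vertical trainer fits on the pretraining
#' surrogate before its base weights seed the horizontal trainers.
#'
#' @inheritParams build_tiny_model
#' @param n_classes number of pretraining classes.
#' @return a `composed_model_spec` with a `NULL` head.
#' @export
build_tiny_pretrain_model <- function(input_shape = c(1L, 32L, 32L),
                                      base_out = 16L, n_classes = 10L) {
  base <- tiny_base_spec(input_shape, base_out, n_classes,
                         classifier_active = TRUE)
  compose(base, NULL)
}

# He-uniform bound for a weight tensor shape (fan_in = prod of all but the
# first dimension for conv/dense weights).
he_bound <- function(shape) {
  fan_in <- if (length(shape) > 1) prod(shape[-1]) else shape
  sqrt(6 / fan_in)
}

#' Initialize a weight bundle for a model spec
#'
#' He-uniform initialization for convolution and dense weights, ones for
#' batch-norm scales, zeros for all biases; deterministic given the seed.
#'
#' @param spec a `model_spec` or `composed_model_spec`.
#' @param seed integer seed.
#' @param namespaces restrict to entries whose name starts with one of these
#'   prefixes (default both `"base/"` and `"head/"`).
#' @return a `weight_bundle`.
#' @export
init_weights <- function(spec, seed, namespaces = c("base/", "head/")) {
  shapes <- spec_param_shapes(spec)
  keep <- grepl(paste0("^(", paste(sub("/$", "", namespaces), collapse = "|"),
                       ")/"), names(shapes))
  shapes <- shapes[keep]
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  entries <- lapply(names(shapes), function(nm) {
    s <- shapes[[nm]]
    if (grepl("\\.bias$", nm)) {
      array(0, dim = s)
    } else if (grepl("norm", nm) && grepl("\\.weight$", nm) && length(s) == 1) {
      array(1, dim = s)
    } else {
      b <- he_bound(s)
      array(stats::runif(prod(s), -b, b), dim = s)
    }
  })
  names(entries) <- names(shapes)
  weight_bundle(entries)
}

# save/restore global RNG state so seeded helpers do not disturb callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Split the base namespace out of a bundle
#'
#' Returns only the `"base/"` entries (the weights W of the shared base
#' model), dropping any head.
#'
#' @param bundle a `weight_bundle`.
#' @return a `weight_bundle` containing only base entries.
#' @export
split_base <- function(bundle) {
  keep <- grepl("^base/", names(bundle$entries))
  if (!any(keep)) abort_structure("bundle contains no 'base/' entries")
  weight_bundle(bundle$entries[keep], round = bundle$round)
}

#' Attach a freshly initialized head to a base bundle
#'
#' Produces the composed weights W∘V: the base entries are carried over
#' bit-exactly and the head parameters V are initialized (He-uniform weights,
#' zero biases) from `init_seed`.
#'
#' @param base_bundle a `weight_bundle` of `"base/"` entries.
#' @param head_spec the head `model_spec`.
#' @param init_seed integer seed for the head initialization.
#' @return a `weight_bundle` with base and head entries.
#' @export
attach_head <- function(base_bundle, head_spec, init_seed) {
  if (!any(grepl("^base/", names(base_bundle$entries))))
    abort_structure("base bundle has no 'base/' entries")
  if (any(grepl("^head/", names(base_bundle$entries))))
    abort_structure("bundle already contains a head")
  head_init <- init_weights(head_spec, seed = init_seed)
  weight_bundle(c(base_bundle$entries, head_init$entries),
                round = base_bundle$round)
}

#' Does a bundle carry head parameters?
#' @param bundle a `weight_bundle`.
#' @return logical.
#' @export
has_head <- function(bundle) any(grepl("^head/", names(bundle$entries)))
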