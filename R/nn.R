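# A small reverse-mode engine for the layer kinds the desk-scale models use
# (conv2d via im2col, max/avg pooling, global average pool, dense, relu,
# series-max), with hand-written SGD-momentum and Adam updates. No installed
# R package provides CNN training, so the engine is implemented here; its
# gradients are validated against central finite differences in the test
# suite. Images are channel-first arrays c(C, H, W); a series exam is a list
# of such arrays.

pad_chw <- function(x, p) {
  if (p == 0L) return(x)
  d <- dim(x)
  out <- array(0, dim = c(d[1], d[2] + 2 * p, d[3] + 2 * p))
  out[, (p + 1):(p + d[2]), (p + 1):(p + d[3])] <- x
  out
}

im2col <- function(x, k, stride, pad) {
  xp <- pad_chw(x, pad)
  d <- dim(xp); C <- d[1]
  Ho <- (d[2] - k) %/% stride + 1L
  Wo <- (d[3] - k) %/% stride + 1L
  A <- array(0, dim = c(C, k, k, Ho * Wo))
  ri <- function(off) off + stride * (0:(Ho - 1))
  ci <- function(off) off + stride * (0:(Wo - 1))
  for (ki in 1:k) for (kj in 1:k) {
    sl <- xp[, ri(ki), ci(kj), drop = FALSE]
    A[, ki, kj, ] <- sl
  }
  dim(A) <- c(C * k * k, Ho * Wo)
  list(cols = A, Ho = Ho, Wo = Wo, C = C,
       Hp = d[2], Wp = d[3])
}

col2im <- function(dcols, info, k, stride, pad, in_dim) {
  dxp <- array(0, dim = c(info$C, info$Hp, info$Wp))
  dim(dcols) <- c(info$C, k, k, info$Ho * info$Wo)
  ri <- function(off) off + stride * (0:(info$Ho - 1))
  ci <- function(off) off + stride * (0:(info$Wo - 1))
  for (ki in 1:k) for (kj in 1:k) {
    contrib <- array(dcols[, ki, kj, ], dim = c(info$C, info$Ho, info$Wo))
    dxp[, ri(ki), ci(kj)] <- dxp[, ri(ki), ci(kj), drop = FALSE] + contrib
  }
  if (pad > 0L)
    dxp <- dxp[, (pad + 1):(pad + in_dim[2]), (pad + 1):(pad + in_dim[3]),
               drop = FALSE]
  dxp
}

forward_one <- function(layer, params, x, train = FALSE) {
  switch(layer$kind,
    conv2d = {
      w <- params[[paste0(layer$name, ".weight")]]
      ic <- im2col(x, layer$kernel, layer$stride, layer$pad)
      wm <- matrix(w, nrow = layer$out_ch)      # out x (in*k*k)
      y <- wm %*% ic$cols
      if (layer$bias) y <- y + as.numeric(params[[paste0(layer$name, ".bias")]])
      out <- array(y, dim = c(layer$out_ch, ic$Ho, ic$Wo))
      list(out = out, cache = list(ic = ic, in_dim = dim(x)))
    },
    dense = {
      w <- params[[paste0(layer$name, ".weight")]]
      y <- as.numeric(w %*% as.numeric(x))
      if (layer$bias) y <- y + as.numeric(params[[paste0(layer$name, ".bias")]])
      list(out = y, cache = list(x = x))
    },
    relu = list(out = pmax(x, 0), cache = list(mask = x > 0)),
    sigmoid = { s <- 1 / (1 + exp(-x)); list(out = s, cache = list(s = s)) },
    dropout = list(out = x, cache = NULL),   # inference/identity behaviour
    flatten = list(out = as.numeric(x), cache = list(in_dim = dim(x))),
    global_avg_pool = {
      d <- dim(x)
      list(out = apply(x, 1, mean), cache = list(in_dim = d))
    },
    max_pool = {
      k <- layer$kernel; s <- layer$stride; p <- layer$pad
      xp <- pad_chw(x, p)
      d <- dim(xp)
      Ho <- (d[2] - k) %/% s + 1L; Wo <- (d[3] - k) %/% s + 1L
      m <- array(-Inf, dim = c(d[1], Ho, Wo))
      for (ki in 1:k) for (kj in 1:k) {
        sl <- xp[, ki + s * (0:(Ho - 1)), kj + s * (0:(Wo - 1)), drop = FALSE]
        m <- pmax(m, sl)
      }
      list(out = m, cache = list(xp = xp, m = m, in_dim = dim(x)))
    },
    avg_pool = {
      k <- layer$kernel; s <- layer$stride
      d <- dim(x)
      Ho <- (d[2] - k) %/% s + 1L; Wo <- (d[3] - k) %/% s + 1L
      acc <- array(0, dim = c(d[1], Ho, Wo))
      for (ki in 1:k) for (kj in 1:k)
        acc <- acc + x[, ki + s * (0:(Ho - 1)), kj + s * (0:(Wo - 1)), drop = FALSE]
      list(out = acc / (k * k), cache = list(in_dim = d))
    },
    stop(sprintf("forward not implemented for layer kind '%s'", layer$kind))
  )
}

backward_one <- function(layer, params, cache, dout, grads) {
  switch(layer$kind,
    conv2d = {
      wname <- paste0(layer$name, ".weight")
      w <- params[[wname]]
      ic <- cache$ic
      dy <- matrix(dout, nrow = layer$out_ch)
      dwm <- dy %*% t(ic$cols)
      grads[[wname]] <- grads[[wname]] + array(dwm, dim = dim(w))
      if (layer$bias) {
        bname <- paste0(layer$name, ".bias")
        grads[[bname]] <- grads[[bname]] + rowSums(dy)
      }
      wm <- matrix(w, nrow = layer$out_ch)
      dcols <- t(wm) %*% dy
      dx <- col2im(dcols, ic, layer$kernel, layer$stride, layer$pad,
                   cache$in_dim)
      list(dx = dx, grads = grads)
    },
    dense = {
      wname <- paste0(layer$name, ".weight")
      w <- params[[wname]]
      grads[[wname]] <- grads[[wname]] + outer(dout, cache$x)
      if (layer$bias) {
        bname <- paste0(layer$name, ".bias")
        grads[[bname]] <- grads[[bname]] + dout
      }
      list(dx = as.numeric(t(w) %*% dout), grads = grads)
    },
    relu = list(dx = dout * cache$mask, grads = grads),
    sigmoid = list(dx = dout * cache$s * (1 - cache$s), grads = grads),
    dropout = list(dx = dout, grads = grads),
    flatten = { dim(dout) <- cache$in_dim; list(dx = dout, grads = grads) },
    global_avg_pool = {
      d <- cache$in_dim
      dx <- array(rep(dout / (d[2] * d[3]), times = d[2] * d[3]), dim = d)
      list(dx = dx, grads = grads)
    },
    max_pool = {
      k <- layer$kernel; s <- layer$stride; p <- layer$pad
      xp <- cache$xp; m <- cache$m
      d <- dim(xp)
      Ho <- dim(m)[2]; Wo <- dim(m)[3]
      dxp <- array(0, dim = d)
      for (ki in 1:k) for (kj in 1:k) {
        rr <- ki + s * (0:(Ho - 1)); cc <- kj + s * (0:(Wo - 1))
        hit <- xp[, rr, cc, drop = FALSE] == m   # ties share the gradient
        dxp[, rr, cc] <- dxp[, rr, cc, drop = FALSE] + dout * hit
      }
      if (p > 0L)
        dxp <- dxp[, (p + 1):(p + cache$in_dim[2]),
                   (p + 1):(p + cache$in_dim[3]), drop = FALSE]
      list(dx = dxp, grads = grads)
    },
    avg_pool = {
      k <- layer$kernel; s <- layer$stride
      d <- cache$in_dim
      Ho <- (d[2] - k) %/% s + 1L; Wo <- (d[3] - k) %/% s + 1L
      dx <- array(0, dim = d)
      for (ki in 1:k) for (kj in 1:k) {
        rr <- ki + s * (0:(Ho - 1)); cc <- kj + s * (0:(Wo - 1))
        dx[, rr, cc] <- dx[, rr, cc, drop = FALSE] + dout / (k * k)
      }
      list(dx = dx, grads = grads)
    },
    stop(sprintf("backward not implemented for layer kind '%s'", layer$kind))
  )
}

active_layers <- function(spec) Filter(function(l) isTRUE(l$in_forward), spec$layers)

forward_layers <- function(layers, params, x) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    r <- forward_one(layers[[i]], params, x)
    x <- r$out
    caches[[i]] <- r$cache
  }
  list(out = x, caches = caches)
}

backward_layers <- function(layers, params, caches, dout, grads) {
  for (i in rev(seq_along(layers))) {
    r <- backward_one(layers[[i]], params, caches[[i]], dout, grads)
    dout <- r$dx
    grads <- r$grads
  }
  list(dx = dout, grads = grads)
}

#' Forward pass of a composed model
#'
#' Runs the forward path of a (composed) model spec on one input. For a
#' series model the input is a list of channel-first slice arrays; the base
#' runs per slice and the head's series-max merges the per-slice feature
#' vectors. Only layers with `in_forward = TRUE` participate.
#'
#' @param spec a `model_spec` or `composed_model_spec` (forward-capable
#'   layer kinds only).
#' @param params named list of parameter arrays (see [bundle_to_params()]).
#' @param x input: a `c(C, H, W)` array, a feature vector, or a list of slice
#'   arrays for series models.
#' @return the network output (logits unless the spec ends in a sigmoid).
#' @export
nn_forward <- function(spec, params, x) {
  nn_forward_cached(spec, params, x)$out
}

nn_forward_cached <- function(spec, params, x) {
  if (inherits(spec, "composed_model_spec")) {
    base_layers <- active_layers(spec$base)
    head_layers <- if (is.null(spec$head)) list() else spec$head$layers
    series_idx <- which(vapply(head_layers, function(l) l$kind, "") == "series_max")
    if (length(series_idx) > 0) {
      stopifnot(is.list(x))
      pre  <- head_layers[seq_len(series_idx - 1L)]     # per-slice head layers
      post <- head_layers[-seq_len(series_idx)]
      slice_caches <- vector("list", length(x))
      feats <- NULL
      for (si in seq_along(x)) {
        fb <- forward_layers(base_layers, params, x[[si]])
        fp <- forward_layers(pre, params, fb$out)
        slice_caches[[si]] <- list(base = fb$caches, pre = fp$caches)
        feats <- rbind(feats, fp$out)
      }
      merged <- apply(feats, 2, max)
      argmax <- apply(feats, 2, which.max)
      fh <- forward_layers(post, params, merged)
      return(list(out = fh$out,
                  cache = list(kind = "series", slice_caches = slice_caches,
                               feats = feats, argmax = argmax,
                               post_caches = fh$caches,
                               base_layers = base_layers, pre = pre,
                               post = post)))
    }
    all_layers <- c(base_layers, head_layers)
    f <- forward_layers(all_layers, params, x)
    return(list(out = f$out, cache = list(kind = "flat", layers = all_layers,
                                          caches = f$caches)))
  }
  f <- forward_layers(active_layers(spec), params, x)
  list(out = f$out, cache = list(kind = "flat", layers = active_layers(spec),
                                 caches = f$caches))
}

zero_grads <- function(params) lapply(params, function(p) array(0, dim = dim(p)))

nn_backward <- function(spec, params, x, cache, dout, grads) {
  if (cache$kind == "flat") {
    return(backward_layers(cache$layers, params, cache$caches, dout, grads)$grads)
  }
  # series model: route gradient through the series max, slice by slice
  fh <- backward_layers(cache$post, params, cache$post_caches, dout, grads)
  grads <- fh$grads
  dmerged <- fh$dx
  n_feat <- length(dmerged)
  for (si in seq_along(x)) {
    dfeat <- numeric(n_feat)
    sel <- cache$argmax == si
    if (!any(sel)) next
    dfeat[sel] <- dmerged[sel]
    bp <- backward_layers(cache$pre, params, cache$slice_caches[[si]]$pre,
                          dfeat, grads)
    grads <- bp$grads
    bb <- backward_layers(cache$base_layers, params,
                          cache$slice_caches[[si]]$base, bp$dx, grads)
    grads <- bb$grads
  }
  grads
}

#' Convert between a weight bundle and a parameter list
#'
#' `bundle_to_params` extracts the named arrays; `params_to_bundle` wraps a
#' parameter list back into a (float32-rounded, name-sorted) bundle.
#'
#' @param bundle a `weight_bundle`.
#' @return a named list of arrays / a `weight_bundle`.
#' @export
bundle_to_params <- function(bundle) bundle$entries

#' @rdname bundle_to_params
#' @param params named list of parameter arrays.
#' @param round round counter to stamp on the bundle.
#' @export
params_to_bundle <- function(params, round = 0L) weight_bundle(params, round = round)

# ---- losses (value + gradient wrt logits) ----

loss_and_grad <- function(loss, z, y, class_wts = NULL, eps = 1e-7) {
  switch(loss,
    weighted_bce = {
      w <- if (is.null(class_wts)) list(w1 = 1, w0 = 1) else class_wts
      p <- 1 / (1 + exp(-z))
      pc <- pmin(pmax(p, eps), 1 - eps)
      l <- -w$w1 * y * log(pc) - w$w0 * (1 - y) * log(1 - pc)
      dz <- -w$w1 * y * (1 - p) + w$w0 * (1 - y) * p
      list(loss = sum(l), dz = dz)
    },
    multilabel_bce = {
      p <- 1 / (1 + exp(-z))
      pc <- pmin(pmax(p, eps), 1 - eps)
      l <- sum(-y * log(pc) - (1 - y) * log(1 - pc))
      list(loss = l, dz = p - y)
    },
    softmax_ce = {
      zs <- z - max(z)
      p <- exp(zs) / sum(exp(zs))
      onehot <- numeric(length(z)); onehot[y + 1L] <- 1
      list(loss = -log(max(p[y + 1L], eps)), dz = p - onehot)
    },
    stop(sprintf("unknown loss '%s'", loss))
  )
}

# ---- optimizers ----

#' Optimizer configuration
#'
#' @param kind `"adam"` or `"sgd"`.
#' @param lr learning rate (> 0).
#' @param weight_decay L2 coefficient added to the gradient.
#' @param momentum SGD momentum.
#' @param beta1,beta2,eps Adam moment decay rates and stabilizer.
#' @return list of class `optimizer_config`.
#' @export
optimizer_config <- function(kind = c("adam", "sgd"), lr = 1e-3,
                             weight_decay = 0, momentum = 0.9,
                             beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  kind <- match.arg(kind)
  if (lr <= 0) abort_validation("learning rate must be positive")
  structure(list(kind = kind, lr = lr, weight_decay = weight_decay,
                 momentum = momentum, beta1 = beta1, beta2 = beta2, eps = eps),
            class = "optimizer_config")
}

new_opt_state <- function(params) {
  list(m = zero_grads(params), v = zero_grads(params), t = 0L)
}

opt_step <- function(cfg, state, params, grads, lr = cfg$lr) {
  if (cfg$weight_decay > 0)
    grads <- Map(function(g, p) g + cfg$weight_decay * p, grads, params)
  if (cfg$kind == "sgd") {
    state$m <- Map(function(v, g) cfg$momentum * v + g, state$m, grads)
    params <- Map(function(p, v) p - lr * v, params, state$m)
  } else {
    state$t <- state$t + 1L
    state$m <- Map(function(m, g) cfg$beta1 * m + (1 - cfg$beta1) * g,
                   state$m, grads)
    state$v <- Map(function(v, g) cfg$beta2 * v + (1 - cfg$beta2) * g^2,
                   state$v, grads)
    bc1 <- 1 - cfg$beta1^state$t
    bc2 <- 1 - cfg$beta2^state$t
    params <- Map(function(p, m, v) p - lr * (m / bc1) / (sqrt(v / bc2) + cfg$eps),
                  params, state$m, state$v)
  }
  list(state = state, params = params)
}

#' Train a model locally for a fixed number of epochs
#'
#' One trainer's local step: load the weights from `bundle`, run
#' `epochs` passes over `data` (seeded shuffling, gradient accumulation over
#' mini-batches), and return the post-trained bundle. Zero epochs returns the
#' bundle unchanged. Optimizer state is created fresh for the call -- each
#' local training session starts with empty moments, as the weights (not the
#' optimizer state) are what the protocol exchanges.
#'
#' @param spec a forward-capable `composed_model_spec`.
#' @param bundle starting `weight_bundle` (must match the spec's shapes).
#' @param data list with `x` (list of inputs) and `y` (labels: 0/1 vector,
#'   class index vector, or n x L 0/1 matrix).
#' @param epochs number of local epochs (0, 1 or 2 in protocol use).
#' @param opt an `optimizer_config`.
#' @param loss `"weighted_bce"`, `"multilabel_bce"` or `"softmax_ce"`.
#' @param class_wts optional [class_weights()] result for `"weighted_bce"`.
#' @param batch_size gradient-accumulation batch size.
#' @param shuffle_seed integer seed for the per-epoch data order.
#' @param lr learning-rate override for this call (defaults to `opt$lr`).
#' @return the post-trained `weight_bundle`, with attribute `loss_history`
#'   (mean training loss per epoch).
#' @export
local_train <- function(spec, bundle, data, epochs, opt, loss = "weighted_bce",
                        class_wts = NULL, batch_size = 4L, shuffle_seed = 1L,
                        lr = opt$lr) {
  check_bundle_matches(spec, bundle)
  if (epochs == 0) return(bundle)
  params <- bundle_to_params(bundle)
  state <- new_opt_state(params)
  n <- length(data$x)
  history <- numeric(epochs)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  for (ep in seq_len(epochs)) {
    set.seed(shuffle_seed + ep - 1L)
    ord <- sample.int(n)
    total <- 0
    i <- 1L
    while (i <= n) {
      idx <- ord[i:min(i + batch_size - 1L, n)]
      grads <- zero_grads(params)
      for (j in idx) {
        x <- data$x[[j]]
        y <- if (is.matrix(data$y)) data$y[j, ] else data$y[j]
        fc <- nn_forward_cached(spec, params, x)
        lg <- loss_and_grad(loss, fc$out, y, class_wts)
        total <- total + lg$loss
        grads <- nn_backward(spec, params, x, fc$cache, lg$dz / length(idx),
                             grads)
      }
      st <- opt_step(opt, state, params, grads, lr = lr)
      state <- st$state
      params <- st$params
      i <- i + batch_size
    }
    history[ep] <- total / n
  }
  out <- params_to_bundle(params, round = bundle$round)
  attr(out, "loss_history") <- history
  out
}

check_bundle_matches <- function(spec, bundle) {
  shapes <- spec_param_shapes(spec)
  nm <- names(bundle$entries)
  if (!setequal(names(shapes), nm))
    abort_structure(sprintf(
      "bundle entries do not match model spec (missing: %s; extra: %s)",
      paste(setdiff(names(shapes), nm), collapse = ", "),
      paste(setdiff(nm, names(shapes)), collapse = ", ")))
  for (k in nm) {
    want <- as.integer(shapes[[k]])
    got <- dim(bundle$entries[[k]])
    if (!identical(as.integer(got), want))
      abort_structure(sprintf("entry '%s' has shape [%s], expected [%s]", k,
                              paste(got, collapse = "x"),
                              paste(want, collapse = "x")))
  }
  invisible(TRUE)
}

#' Predicted scores for a list of inputs
#'
#' @param spec a forward-capable model spec.
#' @param bundle a matching `weight_bundle`.
#' @param xs list of inputs.
#' @param prob apply a sigmoid to the outputs (default TRUE; irrelevant for
#'   ranking metrics such as AUC).
#' @return numeric vector (binary models) or matrix (multi-output models).
#' @export
nn_predict <- function(spec, bundle, xs, prob = TRUE) {
  params <- bundle_to_params(bundle)
  outs <- lapply(xs, function(x) nn_forward(spec, params, x))
  o <- do.call(rbind, outs)
  if (prob && !ends_in_sigmoid(spec)) o <- 1 / (1 + exp(-o))
  if (ncol(o) == 1) as.numeric(o) else o
}

ends_in_sigmoid <- function(spec) {
  layers <- if (inherits(spec, "composed_model_spec")) {
    if (is.null(spec$head)) spec$base$layers else spec$head$layers
  } else spec$layers
  length(layers) > 0 && layers[[length(layers)]]$kind == "sigmoid"
}
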