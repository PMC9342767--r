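# Seeded synthetic image generators. These emulate the statistical skeleton
# of the experimental data -- variable-length exam series with imbalanced
# binary labels, multi-label images with per-label planted patterns, a
# multi-class pretraining surrogate, label noise, and label-skewed non-iid
# splits -- not the photometry of real scans. Positives carry a bright
# Gaussian blob over a smooth anatomy-like background plus pixel noise, so
# separability is controlled by a single signal-strength knob.

smooth_background <- function(h, w) {
  # mixture of low-frequency sinusoids: cheap, smooth, seeded
  fy <- stats::runif(2, 0.5, 2); fx <- stats::runif(2, 0.5, 2)
  py <- stats::runif(2, 0, 2 * pi); px <- stats::runif(2, 0, 2 * pi)
  gy <- seq(0, 2 * pi, length.out = h); gx <- seq(0, 2 * pi, length.out = w)
  b <- outer(sin(fy[1] * gy + py[1]), sin(fx[1] * gx + px[1])) +
       0.5 * outer(cos(fy[2] * gy + py[2]), cos(fx[2] * gx + px[2]))
  0.35 + 0.1 * b
}

gaussian_blob <- function(h, w, cy, cx, sigma, amplitude) {
  gy <- (seq_len(h) - cy)^2; gx <- (seq_len(w) - cx)^2
  amplitude * exp(-outer(gy, gx, "+") / (2 * sigma^2))
}

make_slice <- function(h, w, channels, noise_sd, blob = NULL) {
  img <- array(0, dim = c(channels, h, w))
  bg <- smooth_background(h, w)
  for (c_i in seq_len(channels)) {
    x <- bg + stats::rnorm(h * w, 0, noise_sd)
    if (!is.null(blob)) x <- x + blob
    img[c_i, , ] <- pmin(pmax(x, 0), 1)
  }
  img
}

#' Generate an exam-series dataset with imbalanced binary labels
#'
#' Each exam is a variable-length series of `s` channel-first slices. A
#' positive exam contains a bright Gaussian blob (amplitude
#' `signal_strength * noise_sd` above the background) in at least one slice;
#' negative exams are smooth background plus noise only. At
#' `signal_strength = 0` positives are statistically indistinguishable from
#' negatives. Fully deterministic given the seed.
#'
#' @param n_exams number of exams.
#' @param pos_fraction expected fraction of positive exams, in (0, 1).
#' @param s_range integer range `c(min, max)` of slices per exam.
#' @param image_size side length of the square slices (default 32).
#' @param channels image channels (default 1).
#' @param signal_strength blob amplitude in units of the pixel noise sd.
#' @param noise_sd pixel noise standard deviation (default 0.05).
#' @param seed integer seed.
#' @return object of class `fed_dataset` (kind `"series"`): list with `x`
#'   (list of exams, each a list of `c(C, H, W)` slices) and `y` (0/1
#'   vector).
#' @export
gen_series_dataset <- function(n_exams, pos_fraction, s_range = c(3L, 6L),
                               image_size = 32L, channels = 1L,
                               signal_strength = 4, noise_sd = 0.05,
                               seed = 1L) {
  if (pos_fraction <= 0 || pos_fraction >= 1)
    abort_validation("pos_fraction must be in (0, 1)")
  if (image_size < 8L) abort_validation("image_size too small")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  h <- image_size; w <- image_size
  y <- stats::rbinom(n_exams, 1L, pos_fraction)
  amp <- signal_strength * noise_sd
  x <- vector("list", n_exams)
  for (i in seq_len(n_exams)) {
    s <- sample(s_range[1]:s_range[2], 1L)
    has_blob <- rep(FALSE, s)
    if (y[i] == 1L) {
      has_blob <- stats::runif(s) < 0.7
      if (!any(has_blob)) has_blob[sample.int(s, 1L)] <- TRUE
    }
    exam <- vector("list", s)
    for (si in seq_len(s)) {
      blob <- NULL
      if (has_blob[si])
        blob <- gaussian_blob(h, w, stats::runif(1, h * 0.25, h * 0.75),
                              stats::runif(1, w * 0.25, w * 0.75),
                              sigma = h / 10, amplitude = amp)
      exam[[si]] <- make_slice(h, w, channels, noise_sd, blob)
    }
    x[[i]] <- exam
  }
  structure(list(x = x, y = y, kind = "series"), class = "fed_dataset")
}

#' Generate a multi-label image dataset
#'
#' Each of the `n_labels` labels has a distinct planted spatial pattern (a
#' Gaussian blob at a label-specific grid position); labels are sampled
#' independently with the given prevalences, so co-occurrence arises
#' naturally as in multi-label chest-radiograph data.
#'
#' @param n_images number of images.
#' @param n_labels number of binary labels (default 14).
#' @param prevalence per-label positive rates, recycled to `n_labels`.
#' @param image_size,channels,signal_strength,noise_sd,seed as in
#'   [gen_series_dataset()].
#' @return a `fed_dataset` (kind `"multilabel"`): `x` a list of `c(C, H, W)`
#'   arrays, `y` an `n_images x n_labels` 0/1 matrix.
#' @export
gen_multilabel_dataset <- function(n_images, n_labels = 14L,
                                   prevalence = 0.15, image_size = 32L,
                                   channels = 1L, signal_strength = 4,
                                   noise_sd = 0.05, seed = 1L) {
  prevalence <- rep_len(prevalence, n_labels)
  if (any(prevalence <= 0 | prevalence >= 1))
    abort_validation("prevalences must be in (0, 1)")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  h <- image_size; w <- image_size
  # fixed pattern anchor per label on a grid
  grid_n <- ceiling(sqrt(n_labels))
  anchors <- cbind(
    cy = h * (0.2 + 0.6 * (((seq_len(n_labels) - 1L) %/% grid_n) / max(1, grid_n - 1))),
    cx = w * (0.2 + 0.6 * (((seq_len(n_labels) - 1L) %% grid_n) / max(1, grid_n - 1))))
  amp <- signal_strength * noise_sd
  y <- sapply(prevalence, function(p) stats::rbinom(n_images, 1L, p))
  if (n_images == 1L) y <- matrix(y, nrow = 1L)
  x <- vector("list", n_images)
  for (i in seq_len(n_images)) {
    blob <- NULL
    act <- which(y[i, ] == 1L)
    if (length(act) > 0) {
      blob <- matrix(0, h, w)
      for (c_i in act)
        blob <- blob + gaussian_blob(h, w, anchors[c_i, "cy"],
                                     anchors[c_i, "cx"], sigma = h / 12,
                                     amplitude = amp)
    }
    x[[i]] <- make_slice(h, w, channels, noise_sd, blob)
  }
  structure(list(x = x, y = y, kind = "multilabel"), class = "fed_dataset")
}

#' Generate a multi-class pretraining surrogate
#'
#' Class-specific sinusoidal textures (frequency and orientation determined
#' by the class index) with class-stratified, balanced label counts. Used by
#' the vertical trainer's pretraining phase in place of a large natural-image
#' corpus.
#'
#' @param n_images number of images.
#' @param n_classes number of classes.
#' @param image_size,channels,noise_sd,seed as in [gen_series_dataset()].
#' @return a `fed_dataset` (kind `"pretrain"`): `x` list of arrays, `y`
#'   integer class labels in `0..n_classes-1`.
#' @export
gen_pretrain_dataset <- function(n_images, n_classes = 10L, image_size = 32L,
                                 channels = 1L, noise_sd = 0.1, seed = 1L) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  h <- image_size; w <- image_size
  y <- (seq_len(n_images) - 1L) %% n_classes          # balanced +-1
  y <- y[sample.int(n_images)]
  x <- vector("list", n_images)
  gy <- seq_len(h); gx <- seq_len(w)
  for (i in seq_len(n_images)) {
    cls <- y[i]
    freq <- 0.2 + 0.15 * cls
    theta <- pi * cls / n_classes
    phase <- stats::runif(1, 0, 2 * pi)
    Y <- matrix(gy, h, w); X <- matrix(gx, h, w, byrow = TRUE)
    tex <- 0.5 + 0.25 * sin(freq * (Y * cos(theta) + X * sin(theta)) + phase)
    img <- array(0, dim = c(channels, h, w))
    for (c_i in seq_len(channels))
      img[c_i, , ] <- pmin(pmax(tex + stats::rnorm(h * w, 0, noise_sd), 0), 1)
    x[[i]] <- img
  }
  structure(list(x = x, y = as.integer(y), kind = "pretrain"),
            class = "fed_dataset")
}

#' Flip binary labels at random
#'
#' Each binary label is independently flipped with probability `flip_rate`;
#' the flip mask is recorded in the `flip_mask` attribute so a second
#' application with the same mask restores the original labels.
#'
#' @param dataset a `fed_dataset` with binary labels (vector or matrix).
#' @param flip_rate flip probability in `[0, 0.5)`.
#' @param seed integer seed.
#' @param mask optional explicit logical mask (overrides random draws).
#' @return the dataset with flipped labels; attribute `flip_mask` attached.
#' @export
inject_label_noise <- function(dataset, flip_rate, seed = 1L, mask = NULL) {
  if (is.null(mask)) {
    if (flip_rate < 0 || flip_rate >= 0.5)
      abort_validation("flip_rate must be in [0, 0.5)")
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
    set.seed(seed)
    mask <- stats::runif(length(dataset$y)) < flip_rate
    if (is.matrix(dataset$y)) dim(mask) <- dim(dataset$y)
  }
  dataset$y <- ifelse(mask, 1L - dataset$y, dataset$y)
  attr(dataset, "flip_mask") <- mask
  dataset
}

#' Label-skewed split across trainers
#'
#' Dirichlet label-skew partition: for each class, the class's items are
#' allocated to trainers with proportions drawn from a symmetric
#' Dirichlet(`skew`) distribution. Large `skew` approaches an iid split;
#' small `skew` concentrates each class on few trainers (lower per-trainer
#' label entropy than the global distribution). Shards are disjoint and
#' exhaustive, and every trainer receives at least one item.
#'
#' @param dataset a `fed_dataset` (binary labels; for multi-label data the
#'   first label column drives the skew).
#' @param n_trainers number of shards (>= 2).
#' @param skew Dirichlet concentration parameter (> 0).
#' @param seed integer seed.
#' @return list of `n_trainers` integer index vectors.
#' @export
split_non_iid <- function(dataset, n_trainers, skew, seed = 1L) {
  n <- length(dataset$x)
  if (n_trainers < 2L) abort_validation("need at least 2 trainers")
  if (n_trainers > n) abort_validation("more trainers than items")
  cls <- if (is.matrix(dataset$y)) dataset$y[, 1] else dataset$y
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  shards <- rep(list(integer(0)), n_trainers)
  for (cv in unique(cls)) {
    idx <- which(cls == cv)
    idx <- idx[sample.int(length(idx))]
    g <- stats::rgamma(n_trainers, shape = skew, rate = 1)
    p <- g / sum(g)
    assign_to <- sample.int(n_trainers, length(idx), replace = TRUE, prob = p)
    for (t in seq_len(n_trainers))
      shards[[t]] <- c(shards[[t]], idx[assign_to == t])
  }
  # guarantee non-empty shards by stealing from the largest
  for (t in seq_len(n_trainers)) {
    if (length(shards[[t]]) == 0L) {
      big <- which.max(vapply(shards, length, 1L))
      shards[[t]] <- shards[[big]][1L]
      shards[[big]] <- shards[[big]][-1L]
    }
  }
  lapply(shards, sort)
}

#' Subset a dataset by index
#' @param dataset a `fed_dataset`.
#' @param idx integer indices.
#' @return the sub-dataset.
#' @export
dataset_subset <- function(dataset, idx) {
  out <- dataset
  out$x <- dataset$x[idx]
  out$y <- if (is.matrix(dataset$y)) dataset$y[idx, , drop = FALSE]
           else dataset$y[idx]
  out
}

#' @export
print.fed_dataset <- function(x, ...) {
  cat(sprintf("<fed_dataset> kind '%s', %d items\n", x$kind, length(x$x)))
  invisible(x)
}

# ---- PNG + CSV manifest persistence ----

#' Write / read a dataset as PNG images plus a CSV manifest
#'
#' Slices are written as individual PNG files (grayscale for one channel,
#' RGB for three) and a `manifest.csv` records item ids, slice indices and
#' labels, so standard viewers and loaders can open the data.
#'
#' @param dataset a `fed_dataset` with pixel values in `[0, 1]`.
#' @param dir output directory (created if missing).
#' @return `write_dataset` returns `dir` invisibly; `read_dataset` the
#'   reconstructed `fed_dataset`.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  to_png <- function(img, path) {
    d <- dim(img)
    if (d[1] == 1L) png::writePNG(matrix(img[1, , ], d[2], d[3]), path)
    else png::writePNG(aperm(img, c(2, 3, 1)), path)
  }
  for (i in seq_along(dataset$x)) {
    item <- dataset$x[[i]]
    slices <- if (dataset$kind == "series") item else list(item)
    for (si in seq_along(slices)) {
      fn <- sprintf("item%05d_s%02d.png", i, si)
      to_png(slices[[si]], file.path(dir, fn))
      lab <- if (is.matrix(dataset$y)) paste(dataset$y[i, ], collapse = ";")
             else as.character(dataset$y[i])
      rows[[length(rows) + 1L]] <- data.frame(item = i, slice = si, file = fn,
                                              label = lab)
    }
  }
  manifest <- do.call(rbind, rows)
  manifest$kind <- dataset$kind
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"),
                              stringsAsFactors = FALSE)
  kind <- manifest$kind[1]
  from_png <- function(path) {
    m <- png::readPNG(path)
    if (length(dim(m)) == 2L) array(m, dim = c(1L, nrow(m), ncol(m)))
    else aperm(m, c(3, 1, 2))
  }
  items <- sort(unique(manifest$item))
  x <- vector("list", length(items))
  y_chr <- character(length(items))
  for (k in seq_along(items)) {
    sub <- manifest[manifest$item == items[k], , drop = FALSE]
    sub <- sub[order(sub$slice), , drop = FALSE]
    slices <- lapply(file.path(dir, sub$file), from_png)
    x[[k]] <- if (kind == "series") slices else slices[[1L]]
    y_chr[k] <- as.character(sub$label[1])
  }
  y <- if (any(grepl(";", y_chr))) {
    do.call(rbind, lapply(strsplit(y_chr, ";"), as.integer))
  } else as.integer(y_chr)
  structure(list(x = x, y = y, kind = kind), class = "fed_dataset")
}
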