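# Training-side utilities: the class-weight rule for imbalanced binary
# labels, the weighted and multi-label cross-entropy losses, learning-rate
# schedules (step decay and reduce-on-plateau), the early-sharing partitioner,
# image augmentation, and a rank-based AUC.

#' Class weights from pooled label counts
#'
#' For binary classification over pooled datasets, the positive-class weight
#' is the pooled prevalence `w1 = sum(pos) / sum(total)` and `w0 = 1 - w1`.
#' Note the orientation: `w1` multiplies the positive log-term, so with rare
#' positives the positive class is *down*-weighted -- the opposite of the
#' common inverse-prevalence convention. This is deliberate and matches the
#' loss definition used by the reference training recipe; see the vignette.
#' `conventional = TRUE` swaps the two weights for the inverse-prevalence
#' behaviour.
#'
#' @param pos_counts integer vector of positive-label counts per dataset.
#' @param total_counts integer vector of total exam counts per dataset.
#' @param conventional swap weights to the inverse-prevalence convention
#'   (default `FALSE`).
#' @return list of class `class_weights` with `w1` and `w0`, `w1 + w0 == 1`.
#' @export
class_weights <- function(pos_counts, total_counts, conventional = FALSE) {
  if (length(pos_counts) != length(total_counts))
    abort_validation("pos_counts and total_counts must have equal length")
  if (any(total_counts <= 0)) abort_validation("total counts must be positive")
  sp <- sum(pos_counts); st <- sum(total_counts)
  if (sp <= 0 || sp >= st)
    abort_validation("need 0 < sum(pos) < sum(total)")
  w1 <- sp / st
  if (conventional)
    structure(list(w1 = 1 - w1, w0 = w1), class = "class_weights")
  else
    structure(list(w1 = w1, w0 = 1 - w1), class = "class_weights")
}

#' Weighted binary cross-entropy
#'
#' `L(p, y) = -w1 * y * log(p) - w0 * (1 - y) * log(1 - p)`, with the
#' predicted probability clamped to `[eps, 1 - eps]`. Vectorized; for a
#' batch the loss is the mean over items. With `w1 = w0 = 1` this reduces to
#' the standard (unweighted, per-term) binary cross-entropy.
#'
#' @param p predicted probabilities in `[0, 1]`.
#' @param y binary labels (0/1).
#' @param w a `class_weights` object (or any list with `w1`, `w0`).
#' @param eps clamping constant for the log terms.
#' @param reduce `"mean"` over the batch or `"none"` for per-item losses.
#' @return non-negative loss value(s).
#' @export
weighted_bce <- function(p, y, w, eps = 1e-7, reduce = c("mean", "none")) {
  reduce <- match.arg(reduce)
  pc <- pmin(pmax(p, eps), 1 - eps)
  l <- -w$w1 * y * log(pc) - w$w0 * (1 - y) * log(1 - pc)
  if (reduce == "mean") mean(l) else l
}

#' Multi-label binary cross-entropy
#'
#' Sum over `n_labels` per-class binary cross-entropies (unit weights):
#' `L(p, y) = sum_c [ -y_c log p_c - (1 - y_c) log(1 - p_c) ]`.
#'
#' @param p vector of predicted per-label probabilities.
#' @param y binary label vector of the same length.
#' @param n_labels expected number of labels (default 14).
#' @param eps clamping constant.
#' @return non-negative scalar loss.
#' @export
multilabel_bce <- function(p, y, n_labels = 14L, eps = 1e-7) {
  if (length(p) != n_labels || length(y) != n_labels)
    abort_validation(sprintf("expected %d labels, got %d predictions / %d labels",
                             n_labels, length(p), length(y)))
  pc <- pmin(pmax(p, eps), 1 - eps)
  sum(-y * log(pc) - (1 - y) * log(1 - pc))
}

#' Step-decay learning-rate schedule
#'
#' `lr(ce) = lr0 * 0.5^floor(ce / 2)`: the rate halves every two central
#' epochs, decaying from the *initial* rate (the decay exponent is a function
#' of the epoch index, not applied multiplicatively to the running rate --
#' the latter reading would collapse the rate super-exponentially).
#'
#' @param ce central-epoch index (0-based).
#' @param lr0 initial learning rate.
#' @return the learning rate for central epoch `ce`.
#' @export
step_decay_lr <- function(ce, lr0 = 0.01) {
  if (any(ce < 0)) abort_validation("central-epoch index must be >= 0")
  lr0 * 0.5^(ce %/% 2)
}

#' Reduce-on-plateau learning-rate controller
#'
#' Stateful controller called once per central epoch with the monitored
#' validation metric (lower is better). When the metric has not improved for
#' `patience` consecutive epochs the rate is multiplied by `factor` and the
#' patience counter resets; the best-seen metric is retained, so a sustained
#' plateau triggers repeated reductions.
#'
#' @param lr0 initial learning rate.
#' @param patience epochs without improvement before reducing (default 5).
#' @param factor multiplicative reduction factor (default 0.3).
#' @return an object with `$step(metric)` returning the current rate and
#'   `$lr()` reading it.
#' @export
plateau_controller <- function(lr0, patience = 5L, factor = 0.3) {
  env <- new.env(parent = emptyenv())
  env$lr_val <- lr0; env$best <- Inf; env$bad <- 0L
  env$step <- function(metric) {
    if (metric < env$best) {
      env$best <- metric
      env$bad <- 0L
    } else {
      env$bad <- env$bad + 1L
      if (env$bad >= patience) {
        env$lr_val <- env$lr_val * factor
        env$bad <- 0L
      }
    }
    env$lr_val
  }
  env$lr <- function() env$lr_val
  class(env) <- "plateau_controller"
  env
}

#' Early-sharing partition of local data
#'
#' Uniformly at random (seeded) shuffles the index set and splits it into
#' `n_parts` contiguous chunks whose sizes differ by at most one. A trainer
#' in early-sharing mode trains on one part per turn and shares weights after
#' each part, which reduces the bias any single non-iid shard imprints on the
#' shared model.
#'
#' @param indices vector of item indices (length >= `n_parts`).
#' @param n_parts number of parts (default 20).
#' @param seed integer seed.
#' @return list of class `partition`: disjoint index vectors whose union is
#'   `indices`.
#' @export
partition_early_sharing <- function(indices, n_parts = 20L, seed = 1L) {
  n <- length(indices)
  if (n < n_parts) abort_validation("fewer items than parts")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  shuffled <- indices[sample.int(n)]
  sizes <- rep(n %/% n_parts, n_parts)
  extra <- n %% n_parts
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  ends <- cumsum(sizes)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  structure(Map(function(s, e) shuffled[s:e], starts, ends),
            class = "partition", names = paste0("part", seq_len(n_parts)))
}

#' Augment and normalize an image
#'
#' Random horizontal flip (probability 1/2) and rotation by an angle drawn
#' uniformly from \[-`max_angle`, `max_angle`\] degrees (bilinear, zero
#' fill), followed by per-channel normalization `(x - mean) / sd` with the
#' standard ImageNet statistics by default. Deterministic given the seed.
#'
#' @param image channel-first `c(C, H, W)` array with values in `[0, 1]`.
#' @param seed integer seed.
#' @param max_angle rotation bound in degrees (default 45).
#' @param mean,sd per-channel normalization constants, recycled/truncated to
#'   the channel count.
#' @param flip,angle explicit overrides for the random draws (used to make a
#'   deterministic, normalization-only transform with `flip = FALSE,
#'   angle = 0`).
#' @return normalized `c(C, H, W)` array (values no longer confined to
#'   `[0, 1]`).
#' @export
augment <- function(image, seed = 1L, max_angle = 45,
                    mean = c(0.485, 0.456, 0.406),
                    sd = c(0.229, 0.224, 0.225),
                    flip = NULL, angle = NULL) {
  d <- dim(image)
  if (length(d) != 3L) abort_validation("image must be a c(C, H, W) array")
  C <- d[1]
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  if (is.null(flip)) flip <- stats::runif(1) < 0.5
  if (is.null(angle)) angle <- stats::runif(1, -max_angle, max_angle)
  out <- image
  if (flip) out <- out[, , rev(seq_len(d[3])), drop = FALSE]
  if (angle != 0) {
    for (c_i in seq_len(C)) {
      ch <- matrix(out[c_i, , ], d[2], d[3])
      rot <- EBImage::rotate(ch, angle, output.dim = c(d[2], d[3]), bg.col = 0)
      out[c_i, , ] <- as.matrix(rot)
    }
  }
  mu <- rep_len(mean, C); sg <- rep_len(sd, C)
  for (c_i in seq_len(C)) out[c_i, , ] <- (out[c_i, , ] - mu[c_i]) / sg[c_i]
  out
}

#' Normalize a dataset's pixel values
#'
#' Per-channel standardization `(x - mean) / sd` applied to every image (or
#' every slice of every exam). The defaults are the synthetic generator's
#' background statistics; for natural-image data pass the usual dataset
#' constants. Centering the inputs is what makes the convolutional features
#' sign-diverse -- training directly on `[0, 1]` pixels conditions the
#' problem badly.
#'
#' @param dataset a `fed_dataset`.
#' @param mean,sd per-channel constants, recycled to the channel count.
#' @return the dataset with normalized images.
#' @export
normalize_dataset <- function(dataset, mean = 0.35, sd = 0.15) {
  norm1 <- function(img) {
    C <- dim(img)[1]
    mu <- rep_len(mean, C); sg <- rep_len(sd, C)
    for (c_i in seq_len(C)) img[c_i, , ] <- (img[c_i, , ] - mu[c_i]) / sg[c_i]
    img
  }
  dataset$x <- lapply(dataset$x, function(item) {
    if (is.list(item)) lapply(item, norm1) else norm1(item)
  })
  dataset
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' `AUC = P(score+ > score-) + 0.5 * P(score+ == score-)`, computed from
#' ranks; ties contribute one half. Invariant under strictly monotone
#' transformations of the scores.
#'
#' @param scores numeric prediction scores.
#' @param labels binary labels (0/1); both classes must be present.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L)
    abort_validation("AUC undefined: both classes must be present")
  r <- rank(scores)                       # average ranks handle ties as 0.5
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
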