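test_that("class weights follow the pooled-prevalence rule", {
  w <- class_weights(c(139, 208), c(552, 1130))
  expect_identical(w$w1, 347 / 1682)
  expect_identical(w$w1 + w$w0, 1)
  expect_lt(abs(w$w1 - 0.2063), 5e-5)
  expect_lt(abs(w$w0 - 0.7937), 5e-5)

  expect_identical(class_weights(50, 100)$w1, 0.5)
  expect_lt(abs(class_weights(208, 1130)$w1 - 0.1841), 5e-5)

  expect_error(class_weights(0, 100), class = "fedseal_validation_error")
  expect_error(class_weights(100, 100), class = "fedseal_validation_error")
  expect_error(class_weights(c(1, 1), 100), class = "fedseal_validation_error")

  wc <- class_weights(c(139, 208), c(552, 1130), conventional = TRUE)
  expect_identical(wc$w1, w$w0)
})

test_that("weighted binary cross-entropy evaluates the stated formula", {
  w <- class_weights(c(139, 208), c(552, 1130))
  # chance prediction on a positive: w1 * ln 2
  expect_equal(weighted_bce(0.5, 1, w), w$w1 * log(2))
  expect_lt(abs(weighted_bce(0.5, 1, w) - 0.1430), 1e-4)
  # perfect predictions vanish (up to clamping)
  expect_lt(weighted_bce(1, 1, w), 1e-6)
  expect_lt(weighted_bce(0, 0, w), 1e-6)
  # unit weights reduce to plain binary cross-entropy
  u <- list(w1 = 1, w0 = 1)
  p <- c(0.2, 0.7, 0.95); y <- c(0, 1, 1)
  expect_equal(weighted_bce(p, y, u, reduce = "none"),
               -y * log(p) - (1 - y) * log(1 - p))
  # finite under clamping at the boundaries, non-negative everywhere
  expect_true(is.finite(weighted_bce(0, 1, w)))
  expect_true(all(weighted_bce(runif(20), rbinom(20, 1, .5), w,
                               reduce = "none") >= 0))
})

test_that("multi-label loss is the sum of 14 per-class cross-entropies", {
  y <- rbinom(14, 1, 0.3)
  expect_lt(multilabel_bce(y, y), 1e-5)                 # perfect
  expect_equal(multilabel_bce(rep(0.5, 14), y), 14 * log(2))
  expect_lt(abs(multilabel_bce(rep(0.5, 14), y) - 9.7041), 1e-4)

  set.seed(2)
  p <- runif(14)
  u <- list(w1 = 1, w0 = 1)
  expect_equal(multilabel_bce(p, y),
               sum(weighted_bce(p, y, u, reduce = "none")))

  expect_error(multilabel_bce(runif(5), rbinom(5, 1, .5)),
               class = "fedseal_validation_error")
  expect_equal(multilabel_bce(rep(0.5, 4), c(1, 0, 0, 1), n_labels = 4),
               4 * log(2))
})

test_that("step decay halves the initial rate every two central epochs", {
  expect_identical(step_decay_lr(0), 0.01)
  expect_identical(step_decay_lr(1), 0.01)
  expect_identical(step_decay_lr(2), 0.005)
  expect_identical(step_decay_lr(3), 0.005)
  expect_identical(step_decay_lr(14), 0.01 * 0.5^7)
  expect_equal(step_decay_lr(14), 7.8125e-5)
  lrs <- step_decay_lr(0:14)
  expect_true(all(diff(lrs) <= 0))
  expect_error(step_decay_lr(-1), class = "fedseal_validation_error")
})

test_that("plateau controller reduces by 0.3 after 5 stagnant epochs", {
  ctl <- plateau_controller(1, patience = 5, factor = 0.3)
  for (m in c(5, 4, 3, 2, 1)) ctl$step(m)       # strictly improving
  expect_identical(ctl$lr(), 1)
  for (i in 1:5) ctl$step(1)                    # flat for 5 epochs
  expect_equal(ctl$lr(), 0.3)
  for (i in 1:4) ctl$step(1)
  expect_equal(ctl$lr(), 0.3)                   # patience was reset
  ctl$step(1)
  expect_equal(ctl$lr(), 0.09)                  # second consecutive plateau
})

test_that("early-sharing partition sizes differ by at most one", {
  # one trainer's quarter of the 78,468-image pool into 20 parts
  p <- partition_early_sharing(seq_len(19617), 20, seed = 1)
  sizes <- lengths(p)
  expect_identical(sort(unique(sizes)), c(980L, 981L))
  expect_identical(sum(sizes == 981L), 17L)
  expect_identical(min(sizes), 980L)            # integer part of 19617/20

  one <- partition_early_sharing(5:14, 1, seed = 2)
  expect_length(one, 1)
  expect_identical(sort(one[[1]]), 5:14)        # identity partition
  expect_error(partition_early_sharing(1:5, 10),
               class = "fedseal_validation_error")
})

test_that("partition is a seeded exact cover over many seeds", {
  idx <- 101:300
  for (seed in 1:200) {
    p <- partition_early_sharing(idx, 7, seed = seed)
    all_items <- unname(unlist(p))
    expect_identical(sort(all_items), idx)      # disjoint + exhaustive
    expect_lte(diff(range(lengths(p))), 1L)
  }
  expect_identical(partition_early_sharing(idx, 7, seed = 9),
                   partition_early_sharing(idx, 7, seed = 9))
})

test_that("augmentation normalizes with the stated constants and is seed-stable", {
  # constant image at the channel means -> exactly zero after normalization
  img <- array(0, c(3, 8, 8))
  means <- c(0.485, 0.456, 0.406)
  for (c_i in 1:3) img[c_i, , ] <- means[c_i]
  out <- augment(img, flip = FALSE, angle = 0)
  expect_equal(max(abs(out)), 0)

  set.seed(4)
  img2 <- array(runif(3 * 8 * 8), c(3, 8, 8))
  # normalization-only transform
  out2 <- augment(img2, flip = FALSE, angle = 0)
  expect_equal(out2[2, , ], (img2[2, , ] - 0.456) / 0.224)
  # determinism
  expect_identical(augment(img2, seed = 11), augment(img2, seed = 11))
  expect_false(identical(augment(img2, seed = 11), augment(img2, seed = 12)))
  # shape preserved under rotation+flip
  expect_identical(dim(augment(img2, seed = 13)), dim(img2))
  expect_error(augment(matrix(0, 4, 4)), class = "fedseal_validation_error")
})

test_that("rank AUC equals brute-force pair counting on random instances", {
  brute <- function(s, y) {
    sp <- s[y == 1]; sn <- s[y == 0]
    tot <- 0
    for (a in sp) for (b in sn) tot <- tot + (a > b) + 0.5 * (a == b)
    tot / (length(sp) * length(sn))
  }
  set.seed(55)
  for (i in 1:200) {
    n <- sample(6:25, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    s <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # ties likely
    expect_equal(auc(s, y), brute(s, y))
  }
})

test_that("AUC matches an independent ROC implementation and is rank-invariant", {
  set.seed(66)
  y <- rbinom(60, 1, 0.4)
  s <- rnorm(60) + y
  ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                        direction = "<", levels = c(0, 1))))
  expect_equal(auc(s, y), ref)
  expect_equal(auc(exp(3 * s), y), auc(s, y))   # monotone transform
  expect_identical(auc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  expect_error(auc(s, rep(1, 60)), class = "fedseal_validation_error")
})

test_that("dataset normalization centers the generator's background", {
  ds <- gen_series_dataset(10, 0.3, c(2, 3), 16, 1, signal_strength = 0,
                           seed = 3)
  nd <- normalize_dataset(ds)
  pix <- unlist(lapply(nd$x, function(ex) lapply(ex, as.numeric)))
  expect_lt(abs(mean(pix)), 0.5)   # roughly centered
  expect_identical(nd$y, ds$y)
})
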