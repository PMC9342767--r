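test_that("generators are bit-deterministic given the seed", {
  a <- gen_series_dataset(8, 0.3, c(2, 4), 16, 1, 4, seed = 9)
  b <- gen_series_dataset(8, 0.3, c(2, 4), 16, 1, 4, seed = 9)
  expect_identical(a, b)
  expect_false(identical(a, gen_series_dataset(8, 0.3, c(2, 4), 16, 1, 4,
                                               seed = 10)))
  m1 <- gen_multilabel_dataset(6, 5, 0.2, 16, seed = 3)
  m2 <- gen_multilabel_dataset(6, 5, 0.2, 16, seed = 3)
  expect_identical(m1, m2)
})

test_that("series generator matches the requested imbalance and structure", {
  ds <- gen_series_dataset(1130, 208 / 1130, c(2, 3), 8, 1, 4, seed = 17)
  expect_length(ds$x, 1130)
  n_pos <- sum(ds$y)
  se <- sqrt(1130 * (208 / 1130) * (1 - 208 / 1130))
  expect_lt(abs(n_pos - 208), 3 * se)            # binomial band around 208
  s_lens <- lengths(ds$x)
  expect_true(all(s_lens >= 2 & s_lens <= 3))
  pix <- unlist(ds$x[[1]])
  expect_true(all(pix >= 0 & pix <= 1))
  expect_error(gen_series_dataset(10, 1.2, c(2, 3), 8),
               class = "fedseal_validation_error")
})

test_that("zero signal removes any pixel-level separation between classes", {
  ds <- gen_series_dataset(200, 0.3, c(2, 4), 16, 1, signal_strength = 0,
                           seed = 19)
  feat <- vapply(ds$x, function(ex) max(vapply(ex, mean, 1.0)), 1.0)
  a <- auc(feat, ds$y)
  expect_gt(a, 0.35); expect_lt(a, 0.65)         # indistinguishable
})

test_that("high signal supports >0.9 held-out AUC after two local epochs", {
  fx <- tiny_series_fixture(n_train = 60, n_test = 60, signal_strength = 12,
                            seed = 3)
  spec <- tiny_spec16()
  cw <- class_weights(sum(fx$train$y), length(fx$train$y))
  b <- local_train(spec, init_weights(spec, 5),
                   list(x = fx$train$x, y = fx$train$y), 2L, default_opt(),
                   class_wts = cw, shuffle_seed = 1)
  expect_gt(auc(nn_predict(spec, b, fx$test$x), fx$test$y), 0.9)
})

test_that("held-out AUC is non-decreasing in signal strength", {
  spec <- tiny_spec16()
  aucs <- vapply(c(0, 6, 12), function(sg) {
    fx <- tiny_series_fixture(n_train = 50, n_test = 50, signal_strength = sg,
                              seed = 21)
    cw <- class_weights(max(1, sum(fx$train$y)), length(fx$train$y))
    b <- train_epochs(spec, init_weights(spec, 7), fx$train, 6,
                      class_wts = cw)
    auc(nn_predict(spec, b, fx$test$x), fx$test$y)
  }, 1.0)
  expect_true(all(diff(aucs) >= 0))
})

test_that("multi-label prevalences land within three binomial standard errors", {
  n <- 400L
  prev <- c(0.1, 0.2, 0.3, 0.15)
  ds <- gen_multilabel_dataset(n, 4, prev, 8, seed = 23)
  expect_identical(dim(ds$y), c(n, 4L))
  emp <- colMeans(ds$y)
  se <- sqrt(prev * (1 - prev) / n)
  expect_true(all(abs(emp - prev) <= 3 * se))
  ds14 <- gen_multilabel_dataset(3, seed = 1)
  expect_identical(ncol(ds14$y), 14L)
  expect_error(gen_multilabel_dataset(5, 4, c(0, .2, .2, .2), 8),
               class = "fedseal_validation_error")
})

test_that("per-label AUC exceeds 0.8 at high signal on held-out data", {
  L <- 4
  tr <- normalize_dataset(gen_multilabel_dataset(150, L, 0.25, 16,
                                                 signal_strength = 12,
                                                 seed = 11))
  te <- normalize_dataset(gen_multilabel_dataset(100, L, 0.25, 16,
                                                 signal_strength = 12,
                                                 seed = 12))
  spec <- tiny_spec16(head_out = L, series = FALSE)
  b <- train_epochs(spec, init_weights(spec, 3), tr, 8,
                    loss = "multilabel_bce")
  p <- nn_predict(spec, b, te$x)
  per_label <- vapply(seq_len(L), function(c_i) auc(p[, c_i], te$y[, c_i]), 1.0)
  expect_true(all(per_label > 0.8))
})

test_that("pretraining surrogate has balanced stratified classes", {
  ds <- gen_pretrain_dataset(97, n_classes = 10, image_size = 8, seed = 31)
  expect_true(all(ds$y %in% 0:9))
  counts <- tabulate(ds$y + 1L, 10)
  expect_lte(diff(range(counts)), 1L)
})

test_that("label noise flips the expected fraction and is an involution", {
  ds <- gen_series_dataset(40, 0.3, c(2, 3), 8, 1, 4, seed = 37)
  same <- inject_label_noise(ds, 0)
  expect_identical(same$y, ds$y)

  big <- list(x = as.list(seq_len(10000)), y = rbinom(10000, 1, 0.3),
              kind = "series")
  noisy <- inject_label_noise(structure(big, class = "fed_dataset"), 0.10,
                              seed = 41)
  n_flips <- sum(noisy$y != big$y)
  expect_lt(abs(n_flips - 1000), 3 * sqrt(10000 * 0.1 * 0.9))
  # flipping again with the recorded mask restores the original labels
  restored <- inject_label_noise(noisy, 0.10, mask = attr(noisy, "flip_mask"))
  expect_identical(restored$y, big$y)
  expect_error(inject_label_noise(ds, 0.5), class = "fedseal_validation_error")
})

test_that("label-skew splits are disjoint, exhaustive and entropy-ordered", {
  ds <- gen_series_dataset(300, 0.4, c(2, 3), 8, 1, 4, seed = 43)
  bin_entropy <- function(p) {
    p <- p[p > 0 & p < 1]
    if (length(p) == 0) return(0)
    mean(-p * log2(p) - (1 - p) * log2(1 - p))
  }
  shard_entropy <- function(shards)
    mean(vapply(shards, function(ix) bin_entropy(mean(ds$y[ix])), 1.0))

  for (seed in 1:20) {
    shards <- split_non_iid(ds, 3, skew = 1, seed = seed)
    expect_identical(sort(unlist(shards)), seq_len(300))
    expect_true(all(lengths(shards) > 0))
  }
  global_h <- bin_entropy(mean(ds$y))
  iid <- split_non_iid(ds, 3, skew = 1000, seed = 7)
  skewed <- split_non_iid(ds, 3, skew = 0.05, seed = 7)
  expect_lt(abs(shard_entropy(iid) - global_h), 0.1)
  expect_lt(shard_entropy(skewed), global_h)     # concentration lowers entropy
  expect_error(split_non_iid(ds, 1, 1), class = "fedseal_validation_error")
})

test_that("vertical pretraining does not hurt AUC under 10% label noise", {
  cfg <- list(seed = 1, flip_rate = 0.1, n_exams = c(40L, 40L),
              n_pretrain = 40L, central_epochs = 3L)
  res <- cmd_noisy_label_study(cfg)
  # directional robustness check; small-sample slack of 0.05 AUC documented
  expect_gte(res$auc_difference, -0.05)
  expect_false(is.na(res$auc_pretrained))
  expect_false(is.na(res$auc_scratch))
})

test_that("datasets survive the PNG + manifest round trip up to 8-bit depth", {
  dir <- withr::local_tempdir()
  ds <- gen_series_dataset(4, 0.5, c(2, 3), 8, 1, 6, seed = 51)
  write_dataset(ds, dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  back <- read_dataset(dir)
  expect_identical(back$y, ds$y)
  expect_identical(lengths(back$x), lengths(ds$x))
  err <- max(abs(unlist(back$x) - unlist(ds$x)))
  expect_lt(err, 1 / 255)

  ml <- gen_multilabel_dataset(3, 4, 0.3, 8, seed = 53)
  dir2 <- withr::local_tempdir()
  write_dataset(ml, dir2)
  back2 <- read_dataset(dir2)
  expect_identical(back2$y, ml$y)
})
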