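test_that("composition checks dimensions and treats a null head as identity", {
  base <- model_spec(list(fedseal:::layer_dense("base/fc", 4L, 3L)), 4L, 3L)
  head <- model_spec(list(fedseal:::layer_dense("head/fc", 3L, 2L)), 3L, 2L)
  cm <- compose(base, head)
  expect_identical(cm$input_dim, 4L)
  expect_identical(cm$output_dim, 2L)

  idm <- compose(base, NULL)
  expect_identical(idm$output_dim, base$output_dim)
  expect_null(idm$head)

  bad_head <- model_spec(list(fedseal:::layer_dense("head/fc", 5L, 2L)), 5L, 2L)
  expect_error(compose(base, bad_head), class = "fedseal_composition_error")
})

test_that("a null-head composition computes exactly the base model's output", {
  base <- model_spec(list(fedseal:::layer_dense("base/fc", 4L, 3L),
                          fedseal:::layer_relu()), 4L, 3L)
  b <- init_weights(base, seed = 3)
  x <- rnorm(4)
  expect_identical(nn_forward(compose(base, NULL), bundle_to_params(b), x),
                   nn_forward(base, bundle_to_params(b), x))
})

test_that("dense layer count matches the closed form", {
  m <- model_spec(list(fedseal:::layer_dense("base/fc", 256L, 1L)), 256L, 1L)
  expect_identical(count_trainable(m), 257)
})

test_that("AlexNet-based series model counts match an independent layer-sum oracle", {
  # independent arithmetic: (out*in*k^2 + out) per conv, (out*in + out) per fc
  conv <- function(o, i, k) o * i * k^2 + o
  fc <- function(o, i) o * i + o
  base_expected <- conv(64, 3, 11) + conv(192, 64, 5) + conv(384, 192, 3) +
    conv(256, 384, 3) + conv(256, 256, 3) +
    fc(4096, 9216) + fc(4096, 4096) + fc(1000, 4096)
  expect_identical(count_trainable(build_alexnet_base()), base_expected)
  expect_identical(base_expected, 61100840)

  mri <- build_mri_model()
  expect_identical(count_trainable(mri$head), 257)
  expect_identical(count_trainable(mri), 61101097)
  expect_identical(count_trainable(mri$base) + count_trainable(mri$head),
                   count_trainable(mri))
})

test_that("DenseNet-121 chest model counts match an independent oracle", {
  # independent arithmetic over the dense-block recursion
  conv <- function(o, i, k) o * i * k^2        # bias-free
  bn <- function(ch) 2 * ch
  expected <- conv(64, 3, 7) + bn(64)
  ch <- 64
  for (nb in c(6, 12, 24, 16)) {
    for (l in seq_len(nb)) {
      expected <- expected + bn(ch) + conv(128, ch, 1) + bn(128) +
        conv(32, 128, 3)
      ch <- ch + 32
    }
    if (nb != 16) {
      expected <- expected + bn(ch) + conv(ch / 2, ch, 1)
      ch <- ch / 2
    }
  }
  expected <- expected + bn(ch)                 # final norm, ch == 1024
  xray <- build_xray_model()
  expect_identical(count_trainable(xray$base), expected)
  expect_identical(count_trainable(xray$head), 1024 * 14 + 14)
  expect_identical(count_trainable(xray), 6968206)
})

test_that("the 14-output head emits sigmoid probabilities in (0, 1)", {
  xray <- build_xray_model()
  hb <- init_weights(xray$head, seed = 5)
  set.seed(6)
  out <- nn_forward(xray$head, bundle_to_params(hb), rnorm(1024))
  expect_length(out, 14)
  expect_true(all(out > 0 & out < 1))
})

test_that("tiny model count matches hand arithmetic and its weights survive the codec", {
  tm <- build_tiny_model(c(1L, 32L, 32L), base_out = 16L, head_out = 1L)
  expect_identical(count_trainable(tm),
                   (8 * 1 * 9 + 8) + (16 * 8 * 9 + 16) + (16 + 1))
  withcls <- build_tiny_model(c(1L, 32L, 32L), base_out = 16L,
                              pretrain_classes = 10L)
  expect_identical(count_trainable(withcls),
                   count_trainable(tm) + (10 * 16 + 10))

  k <- kgen()
  b <- init_weights(tm, seed = 2)
  back <- deserialize_weights(aead_decrypt(k, aead_encrypt(k, serialize_weights(b))))
  expect_equal(back$entries, b$entries)
})

test_that("series max over duplicated slices is idempotent (full AlexNet path)", {
  mri <- build_mri_model()
  b <- init_weights(mri, seed = 4)
  params <- bundle_to_params(b)
  set.seed(8)
  slice <- array(runif(3 * 224 * 224), c(3, 224, 224))
  o1 <- nn_forward(mri, params, list(slice))
  o2 <- nn_forward(mri, params, list(slice, slice))
  expect_identical(o1, o2)
  expect_length(o1, 1)
})

test_that("attach_head and split_base are inverse on the base namespace", {
  tm <- build_tiny_model(c(1L, 16L, 16L), base_out = 8L)
  full <- init_weights(tm, seed = 9)
  base_only <- split_base(full)
  expect_true(all(grepl("^base/", names(base_only$entries))))
  expect_false(has_head(base_only))

  w1 <- attach_head(base_only, tm$head, init_seed = 11)
  expect_true(has_head(w1))
  expect_identical(split_base(w1)$entries, base_only$entries)  # W untouched

  w2 <- attach_head(base_only, tm$head, init_seed = 11)
  w3 <- attach_head(base_only, tm$head, init_seed = 12)
  expect_identical(w1$entries, w2$entries)
  expect_false(identical(w1$entries[["head/fc.weight"]],
                         w3$entries[["head/fc.weight"]]))

  expect_error(attach_head(w1, tm$head, 1), class = "fedseal_structure_error")
  head_only <- weight_bundle(full$entries[grepl("^head/", names(full$entries))])
  expect_error(split_base(head_only), class = "fedseal_structure_error")
})

test_that("weight initialization is seed-deterministic with zero biases", {
  tm <- build_tiny_model()
  b1 <- init_weights(tm, seed = 10)
  b2 <- init_weights(tm, seed = 10)
  expect_identical(b1$entries, b2$entries)
  expect_true(all(b1$entries[["base/conv1.bias"]] == 0))
  expect_false(identical(b1$entries, init_weights(tm, seed = 11)$entries))
})
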