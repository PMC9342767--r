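# Shared fixtures: all built in code, seeded.

random_bundle <- function(seed = 1L, n_entries = 3L) {
  set.seed(seed)
  entries <- list()
  for (i in seq_len(n_entries)) {
    ns <- if (i %% 2 == 0) "head/" else "base/"
    d <- sample(1:4, sample(1:3, 1), replace = TRUE)
    entries[[paste0(ns, "t", i)]] <- array(rnorm(prod(d)), dim = d)
  }
  weight_bundle(entries)
}

tiny_series_fixture <- function(n_train = 50L, n_test = 50L,
                                signal_strength = 8, seed = 21L,
                                image_size = 16L) {
  list(
    train = normalize_dataset(gen_series_dataset(
      n_train, 0.3, c(2L, 4L), image_size, 1L, signal_strength, seed = seed)),
    test = normalize_dataset(gen_series_dataset(
      n_test, 0.3, c(2L, 4L), image_size, 1L, signal_strength,
      seed = seed + 1L)))
}

tiny_spec16 <- function(...) build_tiny_model(c(1L, 16L, 16L), base_out = 8L, ...)

default_opt <- function() optimizer_config("adam", lr = 5e-3)

train_epochs <- function(spec, bundle, ds, n_epochs, opt = default_opt(),
                         loss = "weighted_bce", class_wts = NULL) {
  for (ep in seq_len(n_epochs))
    bundle <- local_train(spec, bundle, list(x = ds$x, y = ds$y), 1L, opt,
                          loss = loss, class_wts = class_wts,
                          shuffle_seed = ep)
  bundle
}
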