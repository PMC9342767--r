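# Config-driven experiment entry points: parameter-count report, attack
# demonstrations, the end-to-end vertical-then-horizontal run on synthetic
# series data, and the paired noisy-label study. Every command is a pure
# function of (config, seeds): reruns produce identical reports.

#' Parameter-count report for the reference architectures
#'
#' Builds the composed MRI-series model, the composed chest-radiograph model
#' and a tiny simulation model, and reports their exact trainable-parameter
#' counts; per-layer tables are attached as the `tables` attribute.
#'
#' @return data.frame with columns `model` and `parameters`.
#' @export
cmd_count_params <- function() {
  mri <- build_mri_model()
  xray <- build_xray_model()
  tiny <- build_tiny_model()
  out <- data.frame(
    model = c("mri_composed", "mri_base", "mri_head",
              "xray_composed", "xray_base", "xray_head", "tiny_composed"),
    parameters = c(count_trainable(mri), count_trainable(mri$base),
                   count_trainable(mri$head),
                   count_trainable(xray), count_trainable(xray$base),
                   count_trainable(xray$head), count_trainable(tiny)))
  attr(out, "tables") <- list(mri = param_table(mri), xray = param_table(xray),
                              tiny = param_table(tiny))
  out
}

#' Demonstrate ciphertext attacks against raw CBC and the authenticated codec
#'
#' Encrypts a small weight bundle and applies the selected server-side
#' attack. Against unauthenticated CBC the IV-flip attack is *accepted*: the
#' receiver decrypts, without any error, a first plaintext block equal to the
#' original XOR the attacker's mask. Against the authenticated codec every
#' mode is detected before decryption.
#'
#' @param mode one of `"raw_cbc_iv_flip"`, `"aead_bitflip"`, `"aead_iv_flip"`,
#'   `"replay"`.
#' @param seed integer seed for the demo's randomness.
#' @return list report: the mode, whether the tampered payload was
#'   `accepted` or `detected`, and mode-specific evidence fields.
#' @export
cmd_attack_demo <- function(mode = c("raw_cbc_iv_flip", "aead_bitflip",
                                     "aead_iv_flip", "replay"),
                            seed = 1L) {
  mode <- match.arg(mode)
  key <- kgen(256L)
  spec <- build_tiny_model()
  bundle <- init_weights(spec, seed = seed)
  plain <- serialize_weights(bundle)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  r <- as.raw(sample(0:255, 16L, replace = TRUE))

  if (mode == "raw_cbc_iv_flip") {
    enc <- raw_cbc_encrypt(key$enc_key, plain)
    mod <- cbc_iv_flip_attack(enc$iv, enc$body, r)
    dec <- raw_cbc_decrypt(key$enc_key, mod$iv, mod$body)
    first_ok <- identical(dec[1:16], xor(plain[1:16], r))
    rest_ok <- identical(dec[-(1:16)], plain[-(1:16)])
    return(list(mode = mode, accepted = TRUE, detected = FALSE,
                first_block_is_w_xor_r = first_ok,
                later_blocks_unchanged = rest_ok))
  }

  ct <- aead_encrypt(key, plain)
  tampered <- switch(mode,
    aead_bitflip = { i <- sample.int(length(ct$body) * 8L, 1L) - 1L
      structure(list(iv = ct$iv, body = flip_bit(ct$body, i), tag = ct$tag),
                class = "auth_ciphertext") },
    aead_iv_flip = { m <- cbc_iv_flip_attack(ct$iv, ct$body, r)
      structure(list(iv = m$iv, body = m$body, tag = ct$tag),
                class = "auth_ciphertext") },
    replay = ct)
  if (mode == "replay") {
    # authentic but stale: the MAC passes, the round counter flags it
    server <- new_server("replay")
    b0 <- weight_bundle(bundle$entries, round = 0L)
    ct0 <- aead_encrypt(key, encode_protocol_plaintext(b0))
    b1 <- weight_bundle(bundle$entries, round = 5L)
    ct1 <- aead_encrypt(key, encode_protocol_plaintext(b1))
    server_store(server, ct0); server_store(server, ct1)
    replayed <- server_fetch(server)
    mac_ok <- !inherits(tryCatch(aead_decrypt(key, replayed),
                                 fedseal_integrity_error = function(e) e),
                        "fedseal_integrity_error")
    got <- decode_protocol_plaintext(aead_decrypt(key, replayed))
    return(list(mode = mode, accepted = FALSE, detected = TRUE,
                mac_verifies = mac_ok, stale_round = got$round,
                latest_round = 5L))
  }
  res <- tryCatch(aead_decrypt(key, tampered),
                  fedseal_integrity_error = function(e) e)
  detected <- inherits(res, "fedseal_integrity_error")
  list(mode = mode, accepted = !detected, detected = detected)
}

#' Default configuration for the end-to-end run
#'
#' Desk-scale study conditions: one vertical trainer pretraining on a
#' 10-class texture surrogate, two horizontal trainers on imbalanced
#' high-signal exam-series data, 4 central epochs with runs of at most two
#' local epochs.
#'
#' @param seed master seed.
#' @return named list of configuration values.
#' @export
default_e2e_config <- function(seed = 1L) {
  list(
    seed = seed,
    image_size = 16L, channels = 1L,
    n_pretrain = 60L, n_classes = 4L,
    n_exams = c(60L, 60L),          # per horizontal trainer
    n_test = 60L,
    pos_fraction = 0.3,
    s_range = c(2L, 4L),
    signal_strength = 8,
    base_out = 8L,
    n_horizontal = 2L,
    central_epochs = 4L,
    server_mode = "honest",
    optimizer = "adam", lr = 5e-3, weight_decay = 1e-4,
    batch_size = 4L,
    pretrain = TRUE, pretrain_epochs = 2L,
    flip_rate = 0
  )
}

load_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  base <- default_e2e_config()
  for (nm in names(config)) base[[nm]] <- config[[nm]]
  base
}

build_e2e_trainers <- function(cfg, key) {
  input_shape <- c(cfg$channels, cfg$image_size, cfg$image_size)
  pre_classes <- if (cfg$pretrain) cfg$n_classes else NULL
  spec_h <- build_tiny_model(input_shape, base_out = cfg$base_out,
                             head_out = 1L, series = TRUE,
                             pretrain_classes = pre_classes)
  opt <- optimizer_config(cfg$optimizer, lr = cfg$lr,
                          weight_decay = cfg$weight_decay)
  trainers <- list()
  if (cfg$pretrain) {
    spec_v <- build_tiny_pretrain_model(input_shape, base_out = cfg$base_out,
                                        n_classes = cfg$n_classes)
    pre <- normalize_dataset(gen_pretrain_dataset(cfg$n_pretrain,
                                                  cfg$n_classes,
                                                  cfg$image_size,
                                                  cfg$channels,
                                                  seed = cfg$seed + 100L),
                             mean = 0.5, sd = 0.25)
    trainers[[1]] <- make_trainer(0L, key, spec_v,
                                  list(x = pre$x, y = pre$y), opt,
                                  loss = "softmax_ce", seed = cfg$seed,
                                  vertical = TRUE,
                                  batch_size = cfg$batch_size,
                                  pretrain_epochs = cfg$pretrain_epochs)
  }
  pos <- pos_counts <- integer(0); tot <- integer(0)
  local_sets <- list()
  for (i in seq_len(cfg$n_horizontal)) {
    ds <- gen_series_dataset(cfg$n_exams[min(i, length(cfg$n_exams))],
                             cfg$pos_fraction, cfg$s_range, cfg$image_size,
                             cfg$channels, cfg$signal_strength,
                             seed = cfg$seed + i)
    if (cfg$flip_rate > 0)
      ds <- inject_label_noise(ds, cfg$flip_rate, seed = cfg$seed + 50L + i)
    local_sets[[i]] <- normalize_dataset(ds)
    pos <- c(pos, sum(ds$y == 1L)); tot <- c(tot, length(ds$y))
  }
  cw <- class_weights(pos, tot)
  for (i in seq_len(cfg$n_horizontal)) {
    trainers[[length(trainers) + 1L]] <- make_trainer(
      i, key, build_tiny_model(input_shape, base_out = cfg$base_out,
                               head_out = 1L, series = TRUE,
                               pretrain_classes = pre_classes),
      list(x = local_sets[[i]]$x, y = local_sets[[i]]$y), opt,
      loss = "weighted_bce", class_wts = cw, seed = cfg$seed + 10L * i,
      batch_size = cfg$batch_size)
  }
  list(trainers = trainers, spec_h = spec_h, class_wts = cw)
}

#' End-to-end desk-scale run
#'
#' Generates synthetic data, runs the vertical-then-horizontal protocol
#' through a (possibly malicious) server, and evaluates the final model's
#' AUC on a held-out test set. Deterministic given the config's seed.
#'
#' @param config a config list (see [default_e2e_config()]), a YAML file
#'   path, or `NULL` for the defaults.
#' @param out_dir optional directory for the transcript CSV and JSON report.
#' @return report list: config, schedule, transcript, detection (or NULL),
#'   and `test_auc` for the final bundle (NA if the run was aborted).
#' @export
cmd_e2e <- function(config = NULL, out_dir = NULL) {
  cfg <- load_config(config %||% list())
  key <- kgen(256L)
  built <- build_e2e_trainers(cfg, key)
  schedule <- make_schedule(cfg$n_horizontal, cfg$central_epochs,
                            seed = cfg$seed + 777L)
  server <- new_server(cfg$server_mode, seed = cfg$seed + 999L,
                       tamper_from = cfg$tamper_from %||% 1L)
  run <- run_protocol(built$trainers, server, schedule)
  test_auc <- NA_real_
  if (is.null(run$detection) && !is.null(run$bundle)) {
    test <- normalize_dataset(
      gen_series_dataset(cfg$n_test, cfg$pos_fraction, cfg$s_range,
                         cfg$image_size, cfg$channels,
                         cfg$signal_strength, seed = cfg$seed + 555L))
    scores <- nn_predict(built$spec_h, run$bundle, test$x)
    test_auc <- auc(scores, test$y)
  }
  report <- list(config = cfg, schedule = schedule,
                 transcript = run$transcript, detection = run$detection,
                 test_auc = test_auc,
                 communication = account_communication(run$transcript))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_transcript(run$transcript, file.path(out_dir, "transcript.csv"))
    jsonlite::write_json(
      list(config = cfg, test_auc = test_auc,
           detection = if (is.null(run$detection)) NULL
                       else unclass(run$detection)),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  }
  report
}

#' Paired noisy-label study
#'
#' Runs the end-to-end experiment twice under identical seeds -- once with
#' vertical pretraining, once from random initialization -- on data whose
#' labels are flipped with probability `flip_rate`, and reports both held-out
#' AUCs and their difference. A positive difference indicates pretraining
#' improved robustness to the label noise.
#'
#' @param config config overrides (notably `flip_rate`); see [cmd_e2e()].
#' @return list with `auc_pretrained`, `auc_scratch`, `auc_difference`,
#'   `flip_rate` and the two full reports.
#' @export
cmd_noisy_label_study <- function(config = NULL) {
  cfg <- load_config(config %||% list(flip_rate = 0.1))
  cfg_pre <- cfg; cfg_pre$pretrain <- TRUE
  cfg_raw <- cfg; cfg_raw$pretrain <- FALSE
  rep_pre <- cmd_e2e(cfg_pre)
  rep_raw <- cmd_e2e(cfg_raw)
  list(flip_rate = cfg$flip_rate,
       auc_pretrained = rep_pre$test_auc,
       auc_scratch = rep_raw$test_auc,
       auc_difference = rep_pre$test_auc - rep_raw$test_auc,
       report_pretrained = rep_pre, report_scratch = rep_raw)
}
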