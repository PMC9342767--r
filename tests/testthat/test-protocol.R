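make_ct <- function(key, seed = 1L, round = 0L) {
  b <- weight_bundle(random_bundle(seed)$entries, round = round)
  aead_encrypt(key, fedseal:::encode_protocol_plaintext(b))
}

test_that("the server stores, serves the latest, and starts empty", {
  key <- kgen()
  srv <- new_server("honest")
  expect_null(server_fetch(srv))                      # bottom before any store
  ct1 <- make_ct(key, 1); ct2 <- make_ct(key, 2)
  server_store(srv, ct1)
  got <- server_fetch(srv)
  expect_identical(got$body, ct1$body)                # byte-identical relay
  expect_identical(got$tag, ct1$tag)
  server_store(srv, ct2)
  expect_identical(server_fetch(srv)$body, ct2$body)  # last-writer wins
})

test_that("every tamper mode produces a ciphertext the trainer rejects", {
  key <- kgen()
  for (mode in c("tamper_bitflip", "tamper_iv_xor")) {
    for (seed in 1:15) {
      srv <- new_server(mode, seed = seed)
      server_store(srv, make_ct(key, seed))
      bad <- server_fetch(srv)
      expect_error(aead_decrypt(key, bad), class = "fedseal_integrity_error")
    }
  }
  srv <- new_server("drop")
  server_store(srv, make_ct(key, 1))
  expect_null(server_fetch(srv))
})

test_that("a replayed ciphertext passes the MAC but fails the round check", {
  key <- kgen()
  srv <- new_server("replay")
  server_store(srv, make_ct(key, 1, round = 1L))
  server_store(srv, make_ct(key, 2, round = 2L))
  old_ct <- server_fetch(srv)                  # oldest cached
  expect_silent(plain <- aead_decrypt(key, old_ct))   # authentic
  b <- fedseal:::decode_protocol_plaintext(plain)
  expect_identical(b$round, 1L)

  spec <- tiny_spec16()
  tr <- make_trainer(1L, key, spec, list(x = list(), y = integer(0)),
                     default_opt(), seed = 1)
  tr$last_round <- 2L                          # trainer has already seen round 2
  res <- trainer_round(tr, old_ct, 1L, round_idx = 3L)
  expect_s3_class(res$detection, "detection_event")
  expect_match(res$detection$cause, "stale")
})

test_that("the published 40-entry order satisfies the schedule invariants", {
  o <- mri_training_order()
  expect_length(o, 40)
  expect_identical(sum(o == 1L), 20L)
  expect_identical(sum(o == 2L), 20L)
  expect_lte(max(rle(o)$lengths), 2L)
  expect_true(validate_schedule(o, central_epochs = 20))
})

test_that("generated schedules satisfy the invariants across seeds and shapes", {
  for (seed in 1:150) {
    expect_true(validate_schedule(make_schedule(2, 20, seed = seed), 20))
  }
  for (seed in 1:50) {
    expect_true(validate_schedule(make_schedule(3, 7, seed = seed), 7))
    expect_true(validate_schedule(make_schedule(5, 4, seed = seed), 4))
  }
  expect_identical(make_schedule(2, 20, seed = 3), make_schedule(2, 20, seed = 3))
  expect_identical(make_schedule(1, 2, seed = 1), c(1L, 1L))
  expect_error(make_schedule(1, 3), class = "fedseal_validation_error")
  expect_error(make_schedule(0, 5), class = "fedseal_validation_error")
})

test_that("run-length grouping encodes local-epoch counts and inverts exactly", {
  g <- group_runs(c(1, 2, 2, 1, 1, 2))
  expect_identical(g$trainer, c(1, 2, 1, 2))
  expect_identical(g$epochs, c(1L, 2L, 2L, 1L))
  alt <- rep(c(1, 2), 10)
  expect_true(all(group_runs(alt)$epochs == 1L))
  o <- mri_training_order()
  g2 <- group_runs(o)
  expect_identical(rep(g2$trainer, g2$epochs), o)     # RLE inverse
})

e2e_trainers <- function(cfg, key) fedseal:::build_e2e_trainers(cfg, key)

small_cfg <- function() {
  cfg <- default_e2e_config(seed = 2)
  cfg$n_exams <- c(20L, 20L); cfg$n_pretrain <- 24L
  cfg$central_epochs <- 2L
  cfg
}

test_that("the honest protocol completes with full integrity and loadable weights", {
  cfg <- small_cfg()
  key <- kgen()
  built <- e2e_trainers(cfg, key)
  sched <- make_schedule(2, cfg$central_epochs, seed = 5)
  run <- run_protocol(built$trainers, new_server("honest"), sched)
  expect_null(run$detection)
  expect_true(all(run$transcript$integrity_ok))
  n_groups <- nrow(group_runs(sched))
  # one down + one up per turn, vertical turn included
  expect_identical(nrow(run$transcript), 2L * (n_groups + 1L))
  expect_identical(run$transcript$bytes[1], 0)        # initial bottom fetch
  # the final bundle loads into every horizontal trainer's composed model
  for (tr in built$trainers[-1])
    expect_true(fedseal:::check_bundle_matches(tr$spec, run$bundle))
})

test_that("a tampering server halts the run at the poisoned round, fail-closed", {
  cfg <- small_cfg()
  key <- kgen()
  built <- e2e_trainers(cfg, key)
  sched <- make_schedule(2, cfg$central_epochs, seed = 5)
  srv <- new_server("tamper_bitflip", seed = 3, tamper_from = 3L)
  run <- run_protocol(built$trainers, srv, sched)
  expect_s3_class(run$detection, "detection_event")
  tr <- run$transcript
  detect_round <- tr$round[tr$direction == "detect"]
  expect_length(detect_round, 1)
  expect_identical(max(tr$round), detect_round)       # nothing after detection
  expect_false(all(tr$integrity_ok))
})

test_that("honest protocol and direct hand-off produce bit-identical bundles", {
  cfg <- small_cfg()
  key <- kgen()
  sched <- make_schedule(2, cfg$central_epochs, seed = 5)
  runP <- run_protocol(e2e_trainers(cfg, key)$trainers, new_server("honest"),
                       sched)
  runH <- run_handoff(e2e_trainers(cfg, key)$trainers, sched)
  expect_identical(length(runP$bundle_bytes), length(runH$bundle_bytes))
  expect_identical(runP$bundle_bytes, runH$bundle_bytes)
})

test_that("communication accounting reproduces the full-scale estimates", {
  # 20 central epochs of 234 MB messages, one up+down per epoch per trainer
  alternating <- rep(c(1L, 2L), 20L)
  tr <- transcript_from_schedule(alternating, message_bytes = 234e6)
  acc <- account_communication(tr)
  horiz <- acc[acc$trainer != 0, ]
  expect_equal(horiz$total, c(9.36e9, 9.36e9))
  expect_equal(horiz$up, c(4.68e9, 4.68e9))

  # 4 trainers x 15 central epochs x 20 early-sharing parts of 28 MB uploads
  sched4 <- rep(1:4, times = 15L * 20L)
  tr4 <- transcript_from_schedule(sched4, message_bytes = 28e6)
  acc4 <- account_communication(tr4)
  expect_equal(sum(acc4$up[acc4$trainer != 0]), 33.6e9)   # ~34 GB reported

  # empty transcript sums to zero
  expect_identical(sum(account_communication(tr[0, , drop = FALSE])$total), 0)

  # nominal override recounts desk-scale messages at full-scale size
  cfg <- small_cfg(); key <- kgen()
  run <- run_protocol(e2e_trainers(cfg, key)$trainers, new_server("honest"),
                      rep(c(1L, 2L), cfg$central_epochs))
  acc_n <- account_communication(run$transcript, per_message_bytes = 234e6)
  h <- acc_n[acc_n$trainer == 1, ]
  # 2 turns for trainer 1 -> 2 uploads + 2 non-empty downloads at nominal size
  expect_equal(h$total, 234e6 * 4)
})
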