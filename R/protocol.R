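# The parameter-server protocol. The server stores and relays authenticated
# ciphertexts and never holds a key; trainers decrypt-verify, train locally
# for at most two epochs per turn, re-encrypt and upload. Malicious server
# behaviours (bit flips, IV XOR, replay, drop) are first-class modes, and a
# trainer that receives a non-verifying ciphertext raises a detection event
# and aborts without training (fail-closed). A monotone round counter inside
# the encrypted plaintext lets trainers flag replayed (authentic but stale)
# ciphertexts; this replay guard is an extension beyond the MAC itself and
# can be switched off.

#' Create a central parameter server
#'
#' The server stores the latest ciphertext and serves it on request. It
#' never sees a key. `mode` selects honest or malicious behaviour applied at
#' fetch time: `tamper_bitflip` flips one random bit of the iv/body/tag,
#' `tamper_iv_xor` XORs the IV with a random mask (the classic CBC
#' malleability attack), `replay` serves the oldest cached ciphertext, and
#' `drop` pretends nothing is stored.
#'
#' @param mode one of `"honest"`, `"tamper_bitflip"`, `"tamper_iv_xor"`,
#'   `"replay"`, `"drop"`.
#' @param seed seed for the server's own randomness (tamper positions/masks).
#' @param tamper_from first fetch index (1-based) at which a tampering mode
#'   activates; earlier fetches are served honestly.
#' @return a `param_server` object.
#' @export
new_server <- function(mode = c("honest", "tamper_bitflip", "tamper_iv_xor",
                                "replay", "drop"),
                       seed = 1L, tamper_from = 1L) {
  mode <- match.arg(mode)
  env <- new.env(parent = emptyenv())
  env$stored <- NULL
  env$cache <- list()
  env$mode <- mode
  env$tamper_from <- tamper_from
  env$n_fetches <- 0L
  env$rng <- seed
  class(env) <- "param_server"
  env
}

#' Store a ciphertext on the server
#' @param server a `param_server`.
#' @param ct an `auth_ciphertext`.
#' @return the server, invisibly (state is mutated).
#' @export
server_store <- function(server, ct) {
  stopifnot(inherits(server, "param_server"), inherits(ct, "auth_ciphertext"))
  server$stored <- ct
  server$cache[[length(server$cache) + 1L]] <- ct
  invisible(server)
}

server_rand <- function(server, fn) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(server$rng)
  server$rng <- server$rng + 1L
  fn()
}

#' Fetch the stored ciphertext from the server
#'
#' Returns `NULL` (the bottom element) when nothing has been stored yet, and
#' otherwise the stored ciphertext, transformed according to the server's
#' mode. Maliciousness is modelled, not an error.
#'
#' @param server a `param_server`.
#' @return an `auth_ciphertext` or `NULL`.
#' @export
server_fetch <- function(server) {
  stopifnot(inherits(server, "param_server"))
  server$n_fetches <- server$n_fetches + 1L
  if (is.null(server$stored)) return(NULL)
  active <- server$n_fetches >= server$tamper_from
  ct <- server$stored
  if (!active || server$mode == "honest") return(ct)
  switch(server$mode,
    tamper_bitflip = {
      # flip one random bit anywhere in iv || body || tag
      n_bits <- 8L * (16L + length(ct$body) + 64L)
      bit <- server_rand(server, function() sample.int(n_bits, 1L)) - 1L
      iv <- ct$iv; body <- ct$body; tag <- ct$tag
      if (bit < 128L) {
        iv <- flip_bit(iv, bit)
      } else if (bit < 128L + 8L * length(body)) {
        body <- flip_bit(body, bit - 128L)
      } else {
        tag <- flip_bit(tag, bit - 128L - 8L * length(body))
      }
      structure(list(iv = iv, body = body, tag = tag),
                class = "auth_ciphertext")
    },
    tamper_iv_xor = {
      r <- server_rand(server, function() as.raw(sample(0:255, 16L, replace = TRUE)))
      m <- cbc_iv_flip_attack(ct$iv, ct$body, r)
      structure(list(iv = m$iv, body = m$body, tag = ct$tag),
                class = "auth_ciphertext")
    },
    replay = server$cache[[1L]],
    drop = NULL
  )
}

#' Generate a training order with bounded runs
#'
#' A random order in which each of `n_trainers` trainer ids appears exactly
#' `central_epochs` times and no id occurs more than `max_run` times in a
#' row (a run of length two means the trainer performs two consecutive local
#' epochs before sharing). Sampling is greedy over the feasible candidate
#' set at every position, so the invariants hold by construction;
#' deterministic given the seed.
#'
#' @param n_trainers number of trainer ids (>= 1).
#' @param central_epochs appearances per trainer (>= 1).
#' @param max_run maximum run length (default 2).
#' @param seed integer seed.
#' @return integer vector of trainer ids (1-based).
#' @export
make_schedule <- function(n_trainers, central_epochs, max_run = 2L, seed = 1L) {
  if (n_trainers < 1L || central_epochs < 1L)
    abort_validation("need n_trainers >= 1 and central_epochs >= 1")
  if (n_trainers == 1L && central_epochs > max_run)
    abort_validation("a single trainer cannot satisfy the run bound")
  remaining <- rep(central_epochs, n_trainers)
  ord <- integer(n_trainers * central_epochs)
  last <- 0L; run <- 0L
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  for (pos in seq_along(ord)) {
    cand <- which(remaining > 0L)
    cand <- cand[!(cand == last & run >= max_run)]
    ok <- vapply(cand, function(i) {
      r2 <- remaining; r2[i] <- r2[i] - 1L
      total <- sum(r2)
      all(vapply(which(r2 > 0L), function(j) {
        others <- total - r2[j]
        cap <- if (j == i) (max_run - (if (i == last) run + 1L else 1L)) +
                             max_run * others
               else max_run * (others + 1L) -
                      (if (j == last && i != j) 0L else 0L)
        r2[j] <= cap
      }, TRUE))
    }, TRUE)
    cand <- cand[ok]
    if (length(cand) == 0L)
      abort_validation("schedule constraints infeasible")
    pick <- if (length(cand) == 1L) cand else cand[sample.int(length(cand), 1L)]
    ord[pos] <- pick
    run <- if (pick == last) run + 1L else 1L
    last <- pick
    remaining[pick] <- remaining[pick] - 1L
  }
  ord
}

#' Validate a training order
#'
#' Checks that every trainer id appears exactly `central_epochs` times and
#' that no run exceeds `max_run`.
#'
#' @param order integer vector of trainer ids.
#' @param central_epochs expected appearances per id (default: inferred as
#'   `length(order) / number of distinct ids`).
#' @param max_run maximum allowed run length.
#' @return `TRUE` or `FALSE`.
#' @export
validate_schedule <- function(order, central_epochs = NULL, max_run = 2L) {
  ids <- sort(unique(order))
  if (is.null(central_epochs)) central_epochs <- length(order) / length(ids)
  counts_ok <- all(tabulate(match(order, ids)) == central_epochs)
  runs_ok <- max(rle(order)$lengths) <= max_run
  counts_ok && runs_ok
}

#' Run-length grouping of a training order
#'
#' Collapses consecutive repeats: each group becomes one protocol turn in
#' which the trainer performs `length` local epochs before sharing.
#'
#' @param order integer vector of trainer ids.
#' @return data.frame with columns `trainer` and `epochs`.
#' @export
group_runs <- function(order) {
  r <- rle(order)
  data.frame(trainer = r$values, epochs = r$lengths)
}

#' The published example order for the two-trainer MRI run
#'
#' The canonical 40-entry order for two horizontal trainers over 20 central
#' epochs with runs of at most two consecutive local epochs.
#'
#' @return integer vector of length 40.
#' @export
mri_training_order <- function() {
  c(1L, 2L, 2L, 1L, 1L, 2L, 1L, 2L, 2L, 1L, 1L, 2L, 1L, 2L, 1L, 2L, 2L, 1L,
    1L, 2L, 1L, 2L, 1L, 2L, 1L, 2L, 2L, 1L, 2L, 1L, 1L, 2L, 1L, 2L, 2L, 1L,
    2L, 1L, 1L, 2L)
}

# ---- trainers ----

#' Create a trainer
#'
#' A trainer holds the shared key, its (composed) model spec, its local data
#' and optimizer settings. A vertical trainer (`vertical = TRUE`) has a null
#' head -- its spec IS the base model (possibly with an active pretraining
#' classifier) -- and runs first; horizontal trainers attach their head the
#' first time they receive a base-only bundle.
#'
#' @param id trainer id (0 for the vertical trainer by convention).
#' @param key shared `fedseal_keypair`.
#' @param spec the trainer's `composed_model_spec`.
#' @param data local dataset: list with `x` and `y` as in [local_train()].
#' @param opt an `optimizer_config`.
#' @param loss loss selector for [local_train()].
#' @param class_wts optional class weights.
#' @param seed trainer seed (drives init, head init and data shuffling).
#' @param vertical is this the vertical (pretraining) trainer?
#' @param batch_size mini-batch size.
#' @param pretrain_epochs local epochs for the vertical trainer's single turn.
#' @return a `fed_trainer` environment.
#' @export
make_trainer <- function(id, key, spec, data, opt, loss = "weighted_bce",
                         class_wts = NULL, seed = 1L, vertical = FALSE,
                         batch_size = 4L, pretrain_epochs = 1L) {
  env <- new.env(parent = emptyenv())
  env$id <- id; env$key <- key; env$spec <- spec; env$data <- data
  env$opt <- opt; env$loss <- loss; env$class_wts <- class_wts
  env$seed <- seed; env$vertical <- vertical; env$batch_size <- batch_size
  env$pretrain_epochs <- pretrain_epochs
  env$last_round <- -1L
  class(env) <- "fed_trainer"
  env
}

#' One local training turn on a plaintext bundle
#'
#' The cryptography-free core of a trainer's turn: initialize weights if no
#' bundle exists yet, attach a head on first receipt of a base-only bundle,
#' train for `local_epochs`, and return the post-trained bundle with its
#' round counter advanced. [trainer_round()] wraps this core with
#' decrypt-verify and re-encryption; a serverless hand-off calls it directly,
#' which is what makes the honest protocol bit-equivalent to a direct
#' hand-off.
#'
#' @param trainer a `fed_trainer`.
#' @param bundle incoming `weight_bundle` or `NULL`.
#' @param local_epochs 1 or 2 (0 allowed for accounting-only runs).
#' @param round_idx current protocol round (stamps the outgoing bundle).
#' @return the outgoing `weight_bundle` (attribute `loss_history` attached).
#' @export
trainer_step <- function(trainer, bundle, local_epochs, round_idx) {
  if (is.null(bundle)) {
    bundle <- init_weights(trainer$spec, seed = trainer$seed)
  } else if (!is.null(trainer$spec$head) && !has_head(bundle)) {
    bundle <- attach_head(split_base(bundle), trainer$spec$head,
                          init_seed = trainer$seed + 7919L)
  }
  out <- local_train(trainer$spec, bundle, trainer$data, epochs = local_epochs,
                     opt = trainer$opt, loss = trainer$loss,
                     class_wts = trainer$class_wts,
                     batch_size = trainer$batch_size,
                     shuffle_seed = trainer$seed + 131L * round_idx)
  hist <- attr(out, "loss_history")
  out <- weight_bundle(out$entries, round = round_idx)
  attr(out, "loss_history") <- hist
  out
}

#' A full trainer round against the encrypted channel
#'
#' Decrypt-verifies the payload (a `NULL` payload means no weights exist yet
#' and triggers initialization), runs [trainer_step()], and returns the
#' re-encrypted result. If tag verification fails -- or the embedded round
#' counter is stale while replay protection is on -- a detection event is
#' returned instead and **no training occurs**: weights from a non-verifying
#' ciphertext never influence trainer state.
#'
#' @param trainer a `fed_trainer`.
#' @param payload an `auth_ciphertext` or `NULL`.
#' @param local_epochs local epochs for this turn.
#' @param round_idx current protocol round.
#' @param replay_protect verify the monotone round counter (default TRUE).
#' @return list with either `ciphertext` (an `auth_ciphertext`) and `bundle`
#'   (its plaintext), or `detection` (a `detection_event`).
#' @export
trainer_round <- function(trainer, payload, local_epochs, round_idx,
                          replay_protect = TRUE) {
  bundle <- NULL
  if (!is.null(payload)) {
    plain <- tryCatch(aead_decrypt(trainer$key, payload),
                      fedseal_integrity_error = function(e) e)
    if (inherits(plain, "fedseal_integrity_error"))
      return(list(detection = detection_event(trainer$id, round_idx,
                                              "tag mismatch")))
    bundle <- tryCatch(decode_protocol_plaintext(plain),
                       fedseal_format_error = function(e) e)
    if (inherits(bundle, "fedseal_format_error"))
      return(list(detection = detection_event(trainer$id, round_idx,
                                              "format error")))
    if (replay_protect && bundle$round <= trainer$last_round)
      return(list(detection = detection_event(trainer$id, round_idx,
                                              "stale round (replay)")))
    trainer$last_round <- bundle$round
  }
  out <- trainer_step(trainer, bundle, local_epochs, round_idx)
  trainer$last_round <- round_idx
  ct <- aead_encrypt(trainer$key, encode_protocol_plaintext(out))
  list(ciphertext = ct, bundle = out,
       loss_history = attr(out, "loss_history"))
}

# protocol plaintext = u32 round counter || serialized bundle
encode_protocol_plaintext <- function(bundle) {
  c(le_bytes(bundle$round, 4L), serialize_weights(bundle))
}

decode_protocol_plaintext <- function(plain) {
  if (length(plain) < 4L) abort_format("protocol plaintext too short")
  round <- le_value(plain[1:4])
  b <- deserialize_weights(plain[-(1:4)])
  weight_bundle(b$entries, round = round)
}

detection_event <- function(trainer_id, round, cause) {
  structure(list(trainer = trainer_id, round = round, cause = cause),
            class = "detection_event")
}

#' @export
print.detection_event <- function(x, ...) {
  cat(sprintf("<detection_event> trainer %s flagged round %d: %s\n",
              x$trainer, x$round, x$cause))
  invisible(x)
}

# ---- orchestration ----

transcript_row <- function(round, trainer, direction, bytes, integrity_ok,
                           epochs = NA_integer_, loss = NA_real_) {
  data.frame(round = round, trainer = trainer, direction = direction,
             bytes = bytes, integrity_ok = integrity_ok, epochs = epochs,
             loss = loss)
}

#' Run the vertical-then-horizontal protocol
#'
#' Executes the grouped schedule through the server: the vertical trainer
#' (if present among `trainers`) runs first on an empty server, then each
#' schedule group performs fetch, decrypt-verify, local training, and
#' encrypted upload. Every message is logged in the transcript; on a
#' detection event the run halts cleanly with the event recorded and no
#' further training.
#'
#' @param trainers list of `fed_trainer` objects; horizontal trainers are
#'   indexed by the schedule's ids (1-based into the horizontal list).
#' @param server a `param_server`.
#' @param schedule integer order of horizontal trainer ids.
#' @param replay_protect verify round counters (default TRUE).
#' @return list with `transcript` (data.frame), `bundle` (last verified
#'   `weight_bundle` or NULL), `bundle_bytes` (list of serialized plaintext
#'   bundles per turn, for equivalence checks), and `detection` (event or
#'   NULL).
#' @export
run_protocol <- function(trainers, server, schedule, replay_protect = TRUE) {
  vertical <- Filter(function(t) isTRUE(t$vertical), trainers)
  horizontal <- Filter(function(t) !isTRUE(t$vertical), trainers)
  groups <- group_runs(schedule)
  transcript <- list()
  bundle_bytes <- list()
  last_bundle <- NULL
  round_idx <- 0L

  turn <- function(trainer, epochs, round_idx) {
    payload <- server_fetch(server)
    transcript[[length(transcript) + 1L]] <<- transcript_row(
      round_idx, trainer$id, "down",
      if (is.null(payload)) 0 else ct_size_bytes(payload), TRUE)
    res <- trainer_round(trainer, payload, epochs, round_idx, replay_protect)
    if (!is.null(res$detection)) {
      transcript[[length(transcript) + 1L]] <<- transcript_row(
        round_idx, trainer$id, "detect", 0, FALSE, epochs)
      return(res$detection)
    }
    server_store(server, res$ciphertext)
    transcript[[length(transcript) + 1L]] <<- transcript_row(
      round_idx, trainer$id, "up", ct_size_bytes(res$ciphertext), TRUE,
      epochs, mean(res$loss_history))
    bundle_bytes[[length(bundle_bytes) + 1L]] <<- serialize_weights(res$bundle)
    last_bundle <<- res$bundle
    NULL
  }

  detection <- NULL
  if (length(vertical) > 0) {
    round_idx <- round_idx + 1L
    detection <- turn(vertical[[1L]], vertical[[1L]]$pretrain_epochs %||% 1L,
                      round_idx)
  }
  if (is.null(detection)) {
    for (g in seq_len(nrow(groups))) {
      round_idx <- round_idx + 1L
      detection <- turn(horizontal[[groups$trainer[g]]], groups$epochs[g],
                        round_idx)
      if (!is.null(detection)) break
    }
  }
  list(transcript = do.call(rbind, transcript), bundle = last_bundle,
       bundle_bytes = bundle_bytes, detection = detection)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serverless hand-off baseline
#'
#' Runs the identical vertical-then-horizontal computation with plaintext
#' bundles passed directly from trainer to trainer -- no server, no
#' encryption. With the same seeds, the sequence of bundles is bit-identical
#' to the honest protocol's, which is the transparency property of the
#' encrypted channel.
#'
#' @inheritParams run_protocol
#' @return list with `bundle` and `bundle_bytes` as in [run_protocol()].
#' @export
run_handoff <- function(trainers, schedule) {
  vertical <- Filter(function(t) isTRUE(t$vertical), trainers)
  horizontal <- Filter(function(t) !isTRUE(t$vertical), trainers)
  groups <- group_runs(schedule)
  bundle <- NULL
  bundle_bytes <- list()
  round_idx <- 0L
  if (length(vertical) > 0) {
    round_idx <- round_idx + 1L
    bundle <- trainer_step(vertical[[1L]], NULL,
                           vertical[[1L]]$pretrain_epochs %||% 1L, round_idx)
    bundle_bytes[[length(bundle_bytes) + 1L]] <- serialize_weights(bundle)
  }
  for (g in seq_len(nrow(groups))) {
    round_idx <- round_idx + 1L
    bundle <- trainer_step(horizontal[[groups$trainer[g]]], bundle,
                           groups$epochs[g], round_idx)
    bundle_bytes[[length(bundle_bytes) + 1L]] <- serialize_weights(bundle)
  }
  list(bundle = bundle, bundle_bytes = bundle_bytes)
}

# ---- communication accounting ----

#' Per-trainer communication totals from a transcript
#'
#' Sums transferred bytes by trainer and direction. With `per_message_bytes`
#' set, every non-empty message is counted at that nominal size instead of
#' its actual encoded size -- the way one estimates full-scale costs (e.g. a
#' 234 MB weight ciphertext) from a desk-scale transcript.
#'
#' @param transcript transcript data.frame from [run_protocol()] or
#'   [transcript_from_schedule()].
#' @param per_message_bytes optional nominal size per message.
#' @return data.frame with columns `trainer`, `up`, `down`, `total`.
#' @export
account_communication <- function(transcript, per_message_bytes = NULL) {
  tr <- transcript[transcript$direction %in% c("up", "down"), , drop = FALSE]
  if (!is.null(per_message_bytes))
    tr$bytes <- ifelse(tr$bytes > 0, per_message_bytes, 0)
  ids <- sort(unique(tr$trainer))
  out <- data.frame(
    trainer = ids,
    up = vapply(ids, function(i)
      sum(tr$bytes[tr$trainer == i & tr$direction == "up"]), 1.0),
    down = vapply(ids, function(i)
      sum(tr$bytes[tr$trainer == i & tr$direction == "down"]), 1.0))
  out$total <- out$up + out$down
  out
}

#' Accounting-only transcript for a schedule
#'
#' Builds the message log a protocol run over `schedule` would produce --
#' one fetch and one upload per schedule group, each of `message_bytes` --
#' without doing any training. With `vertical = TRUE` a vertical trainer's
#' initial turn precedes the schedule (its fetch returns the empty marker,
#' logged as 0 bytes), so every horizontal fetch carries a full-size
#' ciphertext.
#'
#' @param schedule integer order of horizontal trainer ids.
#' @param message_bytes nominal ciphertext size.
#' @param vertical include the vertical trainer's initial turn (default TRUE).
#' @return transcript data.frame.
#' @export
transcript_from_schedule <- function(schedule, message_bytes,
                                     vertical = TRUE) {
  groups <- group_runs(schedule)
  rows <- list()
  round_idx <- 0L
  stored <- FALSE
  if (vertical) {
    round_idx <- 1L
    rows[[1]] <- transcript_row(1L, 0L, "down", 0, TRUE)
    rows[[2]] <- transcript_row(1L, 0L, "up", message_bytes, TRUE)
    stored <- TRUE
  }
  for (g in seq_len(nrow(groups))) {
    round_idx <- round_idx + 1L
    rows[[length(rows) + 1L]] <- transcript_row(
      round_idx, groups$trainer[g], "down", if (stored) message_bytes else 0,
      TRUE)
    rows[[length(rows) + 1L]] <- transcript_row(
      round_idx, groups$trainer[g], "up", message_bytes, TRUE,
      groups$epochs[g])
    stored <- TRUE
  }
  do.call(rbind, rows)
}

#' Write a transcript to CSV
#' @param transcript transcript data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_transcript <- function(transcript, path) {
  utils::write.csv(transcript, path, row.names = FALSE)
  invisible(path)
}
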