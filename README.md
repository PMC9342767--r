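# fedseal

Tamper-evident weight exchange for collaborative deep learning through an
untrusted parameter server.

## The problem

Institutions that cannot pool sensitive imaging data can still train a
shared neural network by relaying model weights through a central parameter
server. But a *malicious* server can silently rewrite what it relays: with
unauthenticated CBC encryption, replacing the IV with `IV ⊕ r` hands the
next trainer the weights `W ⊕ r` with no error raised anywhere. `fedseal`
implements the defence — weights travel as authenticated ciphertexts,

    Enc_{Ke‖Ka}(W∘V) = C ‖ HMAC-SHA512_{Ka}(C),   C = AES-256-CBC_{Ke}(W∘V)

with the tag covering the IV, verified in constant time before any
decryption — and simulates the full system around it: vertical model
composition `M∘Mᵢ : ℝᵃ→ℝᶜ` (a pretrained base plus a task head), horizontal
round-robin training with at most two local epochs per turn, malicious
server modes (bit flips, IV XOR, replay, drop), detection events,
transcripts and communication accounting, class-weighted and multi-label
cross-entropy losses, early-sharing partitioning, and seeded synthetic image
generators so everything runs on one CPU in seconds.

It is aimed at people studying secure federated/collaborative training
protocols who want an executable, testable model of the
encrypt-then-MAC + composition design rather than a GPU training framework.

## Worked example

Class weights for pooled imbalanced cohorts (139/552 and 208/1130
positives), the published parameter counts, and an honest end-to-end run:

```r
library(fedseal)

w <- class_weights(c(139, 208), c(552, 1130))
# w1: 0.2063  w0: 0.7937     -- pooled prevalence 347/1682 and its complement

cmd_count_params()[, 1:2]
#           model parameters
# 1  mri_composed   61101097   # AlexNet base + GAP/series-max/256->1 head
# 2      mri_base   61100840
# 3      mri_head        257
# 4 xray_composed    6968206   # DenseNet-121 with a 1024->14 sigmoid head
# 5     xray_base    6953856
# 6     xray_head      14350
# 7 tiny_composed       1265   # desk-scale CNN used by the simulations

rep <- cmd_e2e(default_e2e_config(seed = 1))
rep$test_auc
# [1] 1                        -- held-out AUC, 3 trainers, 4 central epochs
head(rep$transcript[, c("round", "trainer", "direction", "bytes", "integrity_ok")])
#   round trainer direction bytes integrity_ok
# 1     1       0      down     0         TRUE   # vertical trainer finds ⊥
# 2     1       0        up  3150         TRUE   # uploads Enc(W)
# 3     2       1      down  3150         TRUE
# 4     2       1        up  3230         TRUE   # head attached: Enc(W∘V)
# 5     3       2      down  3230         TRUE
```

The attack demonstrations: raw CBC *accepts* the IV-flip forgery and
delivers `W ⊕ r`; the authenticated codec detects it and the protocol halts
at the poisoned round without training on it.

```r
cmd_attack_demo("raw_cbc_iv_flip", seed = 3)
# $accepted TRUE  $first_block_is_w_xor_r TRUE  $later_blocks_unchanged TRUE

cmd_e2e(list(seed = 1, server_mode = "tamper_iv_xor", tamper_from = 3))$detection
# <detection_event> trainer 2 flagged round 3: tag mismatch
```

Schedules with bounded runs (each trainer exactly `central_epochs` times,
never more than two in a row):

```r
make_schedule(2, 10, seed = 7)
# [1] 2 1 1 2 2 1 1 2 2 1 1 2 2 1 2 2 1 2 1 1
```

A run of two (e.g. `1 1`) is one turn of two local epochs before the weights
are re-encrypted and shared. `account_communication()` turns transcripts
into per-trainer byte totals; at full scale (234 MB ciphertexts, 20 central
epochs, one up+down each) that is 9.36 GB per trainer.

See `vignettes/fedseal-methods.Rmd` for the model, the cryptographic
design decisions, what the synthetic generators do and do not emulate, and
known limitations. A thin command-line wrapper over the same functions is
in `inst/cli/fedseal.R`.

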