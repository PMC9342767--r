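---
title: "Tamper-evident weight exchange: models, protocol, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tamper-evident weight exchange: models, protocol, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fedseal)
```

## The problem

Hospitals and research institutions hold imaging data that cannot be pooled,
yet deep models benefit from training on all of it. A common remedy is a
central *parameter server* that relays model weights between trainers. The
threat model addressed here is stronger than the usual honest-but-curious
server: the server may be **malicious** and rewrite the ciphertexts it
relays. `fedseal` implements and simulates a system in which trainers
exchange weights as *authenticated ciphertexts*, so that any server-side
modification is detected by the first receiving trainer, while supporting
two modes of collaboration:

* **vertical training** — trainer 0 trains a base model $M$ on a generic
  corpus; a later trainer composes a task head $M_i$ onto it
  ($M\circ M_i:\mathbb{R}^a\to\mathbb{R}^c$ when
  $M:\mathbb{R}^a\to\mathbb{R}^b$ and $M_i:\mathbb{R}^b\to\mathbb{R}^c$),
  and fine-tunes the composite;
* **horizontal training** — several trainers take turns fitting the shared
  composite on their local data, at most two local epochs per turn.

## Cryptographic construction

The codec is encrypt-then-MAC: with independent uniformly random keys
$K=(K_e, K_a)$,

$$\mathrm{Enc}_{K_e\Vert K_a}(m) = C \,\Vert\, \mathrm{MAC}_{K_a}(C),
\qquad C = \mathrm{AES\text{-}256\text{-}CBC}_{K_e}(\mathrm{iv}, m),$$

with HMAC-SHA512 as the MAC. This composition is the textbook route to
IND-CPA together with INT-CTXT (ciphertext integrity): it is infeasible to
produce a verifying ciphertext that a key holder did not produce. The AES,
HMAC and randomness primitives come from OpenSSL via the `openssl` package;
the package's contribution is the composition and its discipline:

* **the tag covers `iv || body`** — the scheme description leaves open
  whether the IV is authenticated; it must be, because the classic CBC
  malleability attack works purely on the IV: replacing `iv` with
  `iv XOR r` makes the first plaintext block decrypt to $W\oplus r$ with
  every later block intact, and an unauthenticated receiver cannot notice
  (`cbc_iv_flip_attack()` demonstrates this against `raw_cbc_encrypt()`);
* **verify before decrypt**, with a constant-time tag comparison; a failed
  tag yields an integrity error carrying no plaintext material;
* **fresh random IV per encryption** (two encryptions of the same bundle
  differ); PKCS#7 padding; the full 64-byte HMAC-SHA512 tag, untruncated.

Replay is the one manipulation the MAC cannot catch — a replayed ciphertext
is authentic. The protocol therefore embeds a monotone round counter in the
encrypted plaintext; a trainer flags any bundle whose counter is not beyond
the last it has seen. This guard is an extension beyond the core scheme and
can be disabled (`replay_protect = FALSE`).

## Weight bundles

Weights travel as a deterministic binary format (`FSWB`): entries sorted by
name (locale-independent radix order), IEEE-754 binary32 values,
little-endian, with `base/` and `head/` namespaces separating $W$ from $V$.
Determinism matters: the honest-server protocol is required to be *bit*-
equivalent to a direct trainer-to-trainer hand-off, and that property is
only testable if serialization is a pure function of the weights. Parsing
fails closed: truncation or a bad magic yields a format error, never a
partial bundle. At full scale the composed series model's 61,101,097
float32 parameters occupy 244,404,388 payload bytes (~233 MiB), consistent
with the reported on-disk size of roughly 234 MB; the ciphertext adds only
the IV, padding and tag.

## Reference architectures and parameter accounting

Two full-scale layer tables are contractual:

* **Series classifier** (knee-MRI-like): AlexNet base — five convolutions
  (3→64 k11 s4 p2, 64→192 k5 p2, 192→384 k3 p1, 384→256 k3 p1,
  256→256 k3 p1) and the 9216→4096→4096→1000 classifier — plus a head that
  applies global average pooling to each slice's 256×6×6 feature map, a max
  over the series axis ($s\times 256 \to 256$), and a 256→1 logit layer.
  Total: **61,101,097** trainable parameters. The count implies the unused
  ImageNet classifier rides along in the transmitted bundle, so the package
  retains it (`in_forward = FALSE`): counted, serialized, not on the series
  forward path.
* **Multi-label chest classifier**: DenseNet-121 (growth 32, blocks
  6/12/24/16, bias-free convolutions, batch norm) with the 1024→1000
  classifier *replaced* by 1024→14 with sigmoid outputs. Total:
  **6,968,206**.

Counting walks the layer table: $o\,i\,k^2 + o$ per biased convolution,
$o\,i + o$ per dense layer, $2c$ per batch norm. The test suite re-derives
both totals from independent arithmetic oracles. The forward engine
executes the sequential layer kinds (it runs the full AlexNet feature path);
DenseNet-121's concatenative topology is represented for exact counting but
is not executable by the engine — desk-scale simulations use the tiny
family instead, which shares the composition contract.

The **tiny family** (`build_tiny_model()`) is a two-convolution base with
2×2 pooling and global average pooling, an optional ride-along pretraining
classifier, and a linear (optionally series-max) head. It trains in seconds
on a CPU and is the vehicle for all protocol-level experiments.

## Training machinery

* **Class weights.** For pooled imbalanced binary data the loss is
  $L(X,y) = -w(1)\,y\log p - w(0)\,(1-y)\log(1-p)$ with
  $w(1)=\sum\text{pos}/\sum\text{total}$ and $w(0)=1-w(1)$. For the two MRI
  cohorts, $w(1)=347/1682\approx 0.2063$. Note the orientation: $w(1)$
  multiplies the **positive** log-term, so rare positives are
  *down*-weighted — opposite to the usual inverse-prevalence convention.
  The package implements the rule exactly as stated;
  `class_weights(..., conventional = TRUE)` swaps the weights for users who
  want the standard convention.
* **Multi-label loss.** The 14-label objective is the plain sum of
  per-class binary cross-entropies (unit weights).
* **Probability clamping.** Log terms clamp predictions to
  $[\varepsilon, 1-\varepsilon]$ with $\varepsilon=10^{-7}$ (unspecified in
  the source recipe; chosen as the customary float32-safe value).
* **Learning-rate schedules.** The step rule is read as decay *from the
  initial rate*, $\mathrm{lr}(ce)=\mathrm{lr}_0\cdot 0.5^{\lfloor ce/2
  \rfloor}$ — applying the printed factor multiplicatively to the running
  rate every epoch would collapse it super-exponentially, unlike any
  standard schedule. The plateau controller multiplies the rate by 0.3
  after 5 central epochs without improvement of the monitored validation
  loss (validation rather than training loss, since checkpoints are
  selected on validation loss), retains the best metric, and resets its
  patience after each reduction.
* **Optimizers.** SGD with momentum and Adam are implemented in the
  package (no deep-learning runtime exists for R in this toolchain); their
  update rules are the standard ones and the whole reverse-mode engine is
  validated against central finite differences in the test suite (worst
  observed relative error ~2×10⁻⁹). Optimizer moments are local to a
  training call: the protocol exchanges weights, not optimizer state, so
  each turn starts with fresh moments.
* **Early sharing.** A trainer's local indices are shuffled (seeded) and
  split into `n_parts` contiguous chunks differing in size by at most one;
  one pass over a chunk counts as a local epoch. A quarter of a
  78,468-image pool split into 20 parts gives parts of 980–981 images.
* **Augmentation.** Random horizontal flip, rotation uniform in ±45°
  (bilinear, via `EBImage::rotate`), then per-channel normalization with
  the ImageNet constants (means 0.485/0.456/0.406, sds 0.229/0.224/0.225).
* **Input normalization.** `normalize_dataset()` standardizes pixels with
  the generator's background statistics (mean 0.35, sd 0.15 by default).
  This is the desk-scale analogue of the dataset normalization step above,
  and it is load-bearing: training the tiny CNN on raw `[0,1]` pixels
  leaves every global-average-pooled feature nearly collinear with image
  brightness, and convergence from an unlucky sign-inverted initialization
  is extremely slow. Centered inputs restore sign-diverse features and the
  experiments converge in a couple of epochs.
* **AUC.** The Mann–Whitney rank form with average ranks (ties count ½),
  cross-checked in the tests against brute-force pair counting and against
  `pROC`.

## Protocol and server model

The server stores the latest ciphertext and serves it on request; it never
holds a key. Who trains next is driven by the schedule, not the server (the
source system permits either; the fixed published orders match the
schedule-driven reading). `make_schedule()` samples orders in which every
trainer appears exactly `central_epochs` times with runs of length ≤ 2,
using a greedy feasibility-checked draw so the invariants hold by
construction; the published 40-entry two-trainer order validates under the
same predicate. Consecutive appearances merge into one turn of two local
epochs (`group_runs()`).

Malicious behaviours are server *modes* applied at fetch time: a random
single-bit flip in `iv`/`body`/`tag`, the IV-XOR malleability attack, a
replay of the oldest cached ciphertext, or dropping the payload. On any
non-verifying payload the receiving trainer raises a detection event and
the run halts with the event logged — detection, not recovery, is the
specified behaviour; retry/resync policies are left as configuration stubs.
Fail-closed is an invariant: weights from a non-verifying ciphertext never
touch trainer state.

Every message is logged in a transcript (round, trainer, direction, bytes,
integrity flag, training loss). `account_communication()` aggregates bytes
by trainer and direction; with 20 central epochs of 234 MB messages at one
up+down per central epoch, each trainer moves 9.36 GB, matching the
published estimate. That estimate corresponds to an alternating order (all
runs of length 1); merged runs of two local epochs halve the message count,
so grouped orders transfer *less* than the nominal figure.

## Synthetic data: what it does and does not emulate

The generators reproduce the *statistical skeleton* of the experimental
data, not its photometry: variable-length exam series (2–6 slices) with
imbalanced binary labels, where positives carry a bright Gaussian blob
(amplitude = `signal_strength` × pixel-noise sd, sd 0.05) over a smooth
sinusoidal background in at least one slice; multi-label images with one
planted blob position per label and independent per-label prevalences;
class-specific sinusoidal textures as a pretraining surrogate; independent
label flips at a given rate (default study: 10%, the documented noise level
of automatic text-mined labels); and Dirichlet label-skew splits for
non-iid shards. Everything is seeded and bit-reproducible, and datasets can
be written/read as PNG files with a CSV manifest.

Consequently, a passing test suite shows the *protocol, codec, losses and
training loop* behave correctly and that learning signal propagates through
the system — it does not show clinical-grade performance. The full-scale
AUC results (0.924 on the MRI task, 0.8397 averaged over 14 chest labels)
require the original datasets and GPU-scale training and are out of scope
here; the desk-scale experiments replace them with separability,
detection, and equivalence properties.

## Desk-scale study conditions

The default end-to-end configuration (`default_e2e_config()`) uses 16×16
single-channel images, series of 2–4 slices, 60 exams per horizontal
trainer with positive fraction 0.3, signal strength 8 ("high signal"), a
60-exam held-out set, a 60-image 4-class pretraining surrogate, base width
8, Adam (lr 5×10⁻³, weight decay 10⁻⁴), batch size 4, and 4 central epochs
over 2 horizontal trainers plus 1 vertical trainer. These sizes were chosen
once as the smallest configuration in which the planted signal is cleanly
learnable on a CPU in seconds; the separability tests use signal 12 where
the stated condition is "large". Under these conditions the honest run
reaches held-out AUC 1.0 and the tamper modes halt at the first poisoned
round.

Numerical conventions worth knowing: max-pool backward distributes the
gradient equally across tied maxima (ties have probability zero for
continuous inputs); the series-max routes gradient to the arg-max slice
per feature; `weight_bundle()` rounds all values to float32 on
construction, so a bundle is a fixed point of serialize∘deserialize;
degenerate inputs (empty bundles, single-class AUC, fewer items than
partition parts, infeasible schedules) raise typed validation errors rather
than propagating nonsense.

## Known limitations

* The engine is CPU-bound, single-threaded R; it is a simulator, not a
  training framework. DenseNet-121 is counted exactly but not executable.
* The transport is in-process message passing; network timing (the "1 Gbps
  channel") appears only in communication accounting, never as simulated
  latency.
* Byzantine *trainers*, differential privacy, anonymous transmission and
  key management are out of scope; trainers are assumed to be trusted
  cross-silo institutions sharing one pre-distributed key.
* The noisy-label study is directional at desk scale: with strong planted
  signal both arms often saturate, so the test asserts pretraining does not
  hurt (slack 0.05 AUC) rather than a strict improvement.
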