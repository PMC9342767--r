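Package: fedseal
Title: Tamper-Evident Weight Exchange for Distributed Deep Learning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulator and toolkit for collaborative neural-network training
    through an untrusted central parameter server. Model weights are exchanged
    as authenticated ciphertexts (AES-256-CBC under encrypt-then-MAC with
    HMAC-SHA512) so that any server-side tampering is detected by the
    receiving trainer, including the classic CBC IV-malleability attack, which
    is provided as a demonstration against the unauthenticated baseline.
    Supports vertical (base-plus-head model composition) followed by
    horizontal (round-robin) training, class-weighted and multi-label
    cross-entropy losses, early-sharing data partitioning, and seeded
    synthetic image generators for desk-scale experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    openssl,
    EBImage,
    png,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
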