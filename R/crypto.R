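# Authenticated encryption of weight bundles: AES-256-CBC for confidentiality
# composed encrypt-then-MAC with HMAC-SHA512 for ciphertext integrity. The
# AES/HMAC primitives come from OpenSSL (via the openssl package); what this
# file contributes is the composition and its fail-closed verification order:
# the tag covers iv||body and is checked, in constant time, before any
# decryption is attempted. The unauthenticated raw-CBC path and the
# IV-malleability attack are provided to demonstrate why the MAC is needed.

#' Generate a fresh symmetric key pair
#'
#' Draws independent, uniformly random keys from the operating system's
#' cryptographically secure source: a 32-byte AES-256 encryption key and a
#' 64-byte HMAC-SHA512 authentication key.
#'
#' @param bits security parameter; only 256 is supported.
#' @return object of class `fedseal_keypair` with elements `enc_key` (32 raw
#'   bytes) and `mac_key` (64 raw bytes).
#' @export
kgen <- function(bits = 256L) {
  if (!identical(as.integer(bits), 256L))
    abort_validation("only a 256-bit security parameter is supported")
  structure(list(enc_key = openssl::rand_bytes(32L),
                 mac_key = openssl::rand_bytes(64L)),
            class = "fedseal_keypair")
}

#' @export
print.fedseal_keypair <- function(x, ...) {
  cat("<fedseal_keypair> enc_key: 32 bytes, mac_key: 64 bytes (values hidden)\n")
  invisible(x)
}

# Constant-time byte comparison: accumulates XOR differences over the full
# length instead of short-circuiting at the first mismatch.
const_time_equal <- function(a, b) {
  if (length(a) != length(b)) return(FALSE)
  sum(as.integer(xor(a, b))) == 0L
}

hmac_tag <- function(mac_key, iv, body) {
  tag <- openssl::sha512(c(iv, body), key = mac_key)
  attributes(tag) <- NULL
  tag
}

#' Authenticated encryption of a byte string
#'
#' Encrypt-then-MAC: the plaintext is padded (PKCS#7) and encrypted with
#' AES-256-CBC under a fresh random IV, then HMAC-SHA512 is computed over
#' `iv || body`. Encrypting the same plaintext twice yields different
#' ciphertexts because the IV is fresh on every call.
#'
#' @param key a `fedseal_keypair` from [kgen()].
#' @param plaintext non-empty raw vector.
#' @return object of class `auth_ciphertext` with elements `iv` (16 bytes),
#'   `body` (multiple of 16 bytes) and `tag` (64 bytes).
#' @export
aead_encrypt <- function(key, plaintext) {
  stopifnot(inherits(key, "fedseal_keypair"))
  if (!is.raw(plaintext) || length(plaintext) == 0L)
    abort_validation("plaintext must be a non-empty raw vector")
  iv <- openssl::rand_bytes(16L)
  body <- openssl::aes_cbc_encrypt(plaintext, key = key$enc_key, iv = iv)
  attributes(body) <- NULL
  structure(list(iv = iv, body = body, tag = hmac_tag(key$mac_key, iv, body)),
            class = "auth_ciphertext")
}

#' Verify and decrypt an authenticated ciphertext
#'
#' Recomputes the HMAC-SHA512 tag over `iv || body` and compares it to the
#' stored tag in constant time, *before* any decryption. On mismatch an
#' integrity error (condition class `fedseal_integrity_error`) is raised and
#' no plaintext material is produced; this is the signal that the parameter
#' server (or channel) modified the ciphertext. A padding failure after a
#' valid tag cannot occur for honestly produced ciphertexts and is treated as
#' fatal.
#'
#' @param key a `fedseal_keypair`.
#' @param ct an `auth_ciphertext`.
#' @return the original plaintext raw vector.
#' @export
aead_decrypt <- function(key, ct) {
  stopifnot(inherits(key, "fedseal_keypair"))
  if (!inherits(ct, "auth_ciphertext")) abort_format("expected an auth_ciphertext")
  if (length(ct$iv) != 16L || length(ct$tag) != 64L ||
      length(ct$body) %% 16L != 0L || length(ct$body) == 0L)
    abort_integrity("malformed ciphertext fields")
  if (!const_time_equal(hmac_tag(key$mac_key, ct$iv, ct$body), ct$tag))
    abort_integrity()
  tryCatch(
    openssl::aes_cbc_decrypt(ct$body, key = key$enc_key, iv = ct$iv),
    error = function(e) stop("fatal: padding failure after a valid tag (key mismatch?)")
  )
}

#' Unauthenticated CBC encryption (attack baseline)
#'
#' Plain AES-256-CBC with PKCS#7 padding and no authentication tag. This is
#' the malleable construction that [cbc_iv_flip_attack()] defeats; it exists
#' only to demonstrate the attack and must never be used to move weights.
#'
#' @param enc_key 32-byte raw AES-256 key.
#' @param plaintext non-empty raw vector.
#' @param iv optional 16-byte IV (fresh random if omitted).
#' @return list with `iv` and `body`.
#' @export
raw_cbc_encrypt <- function(enc_key, plaintext, iv = NULL) {
  if (is.null(iv)) iv <- openssl::rand_bytes(16L)
  if (length(iv) != 16L) abort_validation("iv must be 16 bytes")
  body <- openssl::aes_cbc_encrypt(plaintext, key = enc_key, iv = iv)
  attributes(body) <- NULL
  list(iv = iv, body = body)
}

#' @rdname raw_cbc_encrypt
#' @param body CBC ciphertext bytes.
#' @export
raw_cbc_decrypt <- function(enc_key, iv, body) {
  tryCatch(
    openssl::aes_cbc_decrypt(body, key = enc_key, iv = iv),
    error = function(e) abort_padding()
  )
}

#' The CBC IV-malleability attack
#'
#' A malicious server holding `(iv, body)` can replace the IV with `iv XOR r`
#' for any chosen 16-byte mask `r`. Under unauthenticated CBC the receiver
#' then decrypts to `W XOR r` on the first plaintext block with all later
#' blocks unchanged, and has no way to notice. Applying the same modification
#' to an authenticated ciphertext makes [aead_decrypt()] fail, because the
#' MAC covers the IV.
#'
#' @param iv 16-byte IV.
#' @param body CBC ciphertext.
#' @param r 16-byte mask chosen by the attacker.
#' @return list with the modified `iv` and the untouched `body`.
#' @export
cbc_iv_flip_attack <- function(iv, body, r) {
  if (length(r) != 16L) abort_validation("mask r must be one 16-byte block")
  list(iv = xor(iv, r), body = body)
}

#' Flip a single bit of a raw vector
#'
#' Utility used by the tamper-mode server and the integrity test-suite:
#' returns `x` with bit `bit_index` (0-based over the whole vector, LSB-first
#' within a byte) inverted.
#'
#' @param x raw vector.
#' @param bit_index 0-based bit position in `[0, 8*length(x))`.
#' @return modified raw vector.
#' @export
flip_bit <- function(x, bit_index) {
  byte <- bit_index %/% 8L + 1L
  bit <- bit_index %% 8L
  if (byte > length(x)) abort_validation("bit index out of range")
  x[byte] <- xor(x[byte], as.raw(bitwShiftL(1L, bit)))
  x
}

# -- ciphertext wire/file format: magic "FSCT", u16 version, 16-byte iv,
#    u64 body length, body, 64-byte tag --

#' Serialize / deserialize an authenticated ciphertext
#' @param ct an `auth_ciphertext`.
#' @return `ct_serialize` returns a raw vector; `ct_deserialize` the ciphertext.
#' @export
ct_serialize <- function(ct) {
  stopifnot(inherits(ct, "auth_ciphertext"))
  c(CT_MAGIC, le_bytes(1L, 2L), ct$iv, le_bytes(length(ct$body), 8L),
    ct$body, ct$tag)
}

#' @rdname ct_serialize
#' @param data raw vector produced by `ct_serialize`.
#' @export
ct_deserialize <- function(data) {
  rd <- new_reader(data)
  if (!identical(take(rd, 4L), CT_MAGIC))
    abort_format("bad magic: not a ciphertext stream")
  ver <- le_value(take(rd, 2L))
  if (ver != 1) abort_format(sprintf("unsupported ciphertext version %d", ver))
  iv <- take(rd, 16L)
  body_len <- le_value(take(rd, 8L))
  body <- take(rd, body_len)
  tag <- take(rd, 64L)
  if (rd$pos != length(data) + 1L) abort_format("trailing bytes in ciphertext stream")
  structure(list(iv = iv, body = body, tag = tag), class = "auth_ciphertext")
}

#' Total encoded size of a ciphertext in bytes
#' @param ct an `auth_ciphertext`.
#' @return number of bytes of its serialized form.
#' @export
ct_size_bytes <- function(ct) 4 + 2 + 16 + 8 + length(ct$body) + 64

#' @export
print.auth_ciphertext <- function(x, ...) {
  cat(sprintf("<auth_ciphertext> body %d bytes (+16 iv, +64 tag)\n",
              length(x$body)))
  invisible(x)
}
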