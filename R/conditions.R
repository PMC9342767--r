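# Structured error conditions. Every error raised by the package carries the
# class "fedseal_error" plus a specific subclass so callers (and the protocol
# layer) can distinguish an integrity failure from, say, a malformed file.

fedseal_abort <- function(class, message, ...) {
  stop(errorCondition(message, ..., class = c(class, "fedseal_error")))
}

#' @keywords internal
abort_integrity <- function(message = "authentication tag mismatch: ciphertext was modified") {
  fedseal_abort("fedseal_integrity_error", message)
}

abort_format <- function(message) {
  fedseal_abort("fedseal_format_error", message)
}

abort_padding <- function(message = "CBC padding invalid on decryption") {
  fedseal_abort("fedseal_padding_error", message)
}

abort_validation <- function(message) {
  fedseal_abort("fedseal_validation_error", message)
}

abort_composition <- function(message) {
  fedseal_abort("fedseal_composition_error", message)
}

abort_structure <- function(message) {
  fedseal_abort("fedseal_structure_error", message)
}
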