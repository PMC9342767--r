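# Weight bundles: the canonical, deterministic representation of a model's
# parameters that travels over the wire. Values are 32-bit floats; entries are
# kept sorted by name (radix order, locale-independent) so the same bundle
# always serializes to identical bytes.

#' Round numeric values to 32-bit float precision
#'
#' Weight bundles store IEEE-754 binary32 values. This helper maps doubles to
#' the nearest representable float32 (via an actual binary round trip), so a
#' bundle is bit-stable under serialization.
#'
#' @param x numeric vector or array.
#' @return object of the same shape whose values are exactly representable in
#'   32-bit floating point.
#' @export
as_float32 <- function(x) {
  d <- dim(x)
  y <- readBin(writeBin(as.numeric(x), raw(), size = 4L, endian = "little"),
               "numeric", n = length(x), size = 4L, endian = "little")
  dim(y) <- d
  y
}

#' Create a weight bundle
#'
#' A weight bundle is an ordered, named collection of real-valued arrays
#' (model parameters). Names use the `"base/"` or `"head/"` namespace prefix
#' to mark which part of a composed model they belong to. Entries are sorted
#' by name so that serialization is deterministic; all values are rounded to
#' 32-bit float precision on construction.
#'
#' @param entries named list of numeric arrays (names must be unique and
#'   prefixed `"base/"` or `"head/"`).
#' @param round integer round counter carried by the protocol layer (used for
#'   replay detection); default 0.
#' @return object of class `weight_bundle`.
#' @export
weight_bundle <- function(entries, round = 0L) {
  nm <- names(entries)
  if (length(entries) > 0 && (is.null(nm) || any(nm == "") || anyDuplicated(nm)))
    abort_validation("bundle entries must have unique non-empty names")
  if (length(entries) > 0 && !all(grepl("^(base|head)/", nm)))
    abort_validation("bundle entry names must be prefixed 'base/' or 'head/'")
  for (i in seq_along(entries)) {
    v <- entries[[i]]
    if (!is.numeric(v)) abort_validation(sprintf("entry '%s' is not numeric", nm[i]))
    if (!all(is.finite(v)))
      abort_validation(sprintf("entry '%s' contains non-finite values", nm[i]))
  }
  ord <- if (length(entries)) order(names(entries), method = "radix")
         else integer(0)
  entries <- lapply(entries[ord], function(v) {
    if (is.null(dim(v))) dim(v) <- length(v)
    as_float32(v)
  })
  structure(list(entries = entries, round = as.integer(round)),
            class = "weight_bundle")
}

#' @export
print.weight_bundle <- function(x, ...) {
  cat(sprintf("<weight_bundle> %d entries, %s parameters, round %d\n",
              length(x$entries),
              format(sum(vapply(x$entries, length, 1L)), big.mark = ","),
              x$round))
  for (nm in names(x$entries))
    cat(sprintf("  %-28s [%s]\n", nm, paste(dim(x$entries[[nm]]), collapse = "x")))
  invisible(x)
}

#' Number of scalar parameters in a bundle
#' @param bundle a `weight_bundle`.
#' @return integer-valued count.
#' @export
bundle_n_params <- function(bundle) {
  sum(vapply(bundle$entries, function(e) as.numeric(length(e)), 1.0))
}

# -- little-endian integer helpers (u16/u32 fit in R integers; u64 is written
#    byte-wise so sizes up to 2^53 are exact) --

le_bytes <- function(x, n) as.raw((x %/% 256^(0:(n - 1))) %% 256)
le_value <- function(b) sum(as.numeric(b) * 256^(seq_along(b) - 1))

BUNDLE_MAGIC <- charToRaw("FSWB")
CT_MAGIC     <- charToRaw("FSCT")

#' Serialize a weight bundle to bytes
#'
#' Deterministic, versioned binary encoding: magic `"FSWB"`, u16 version, u32
#' entry count, then per entry a u16 name length, the UTF-8 name, a u8 rank,
#' the dimensions as u64 values, and the raw little-endian float32 payload.
#' The same bundle always yields identical bytes.
#'
#' @param bundle a `weight_bundle`.
#' @return raw vector.
#' @export
serialize_weights <- function(bundle) {
  if (!inherits(bundle, "weight_bundle"))
    abort_validation("serialize_weights() expects a weight_bundle")
  con <- rawConnection(raw(0), "wb")
  on.exit(close(con))
  writeBin(BUNDLE_MAGIC, con)
  writeBin(le_bytes(1L, 2L), con)                       # version
  writeBin(le_bytes(length(bundle$entries), 4L), con)   # entry count
  for (nm in names(bundle$entries)) {
    v <- bundle$entries[[nm]]
    name_raw <- charToRaw(enc2utf8(nm))
    writeBin(le_bytes(length(name_raw), 2L), con)
    writeBin(name_raw, con)
    d <- dim(v)
    writeBin(as.raw(length(d)), con)                    # rank (u8)
    for (dd in d) writeBin(le_bytes(dd, 8L), con)
    writeBin(as.numeric(v), con, size = 4L, endian = "little")
  }
  rawConnectionValue(con)
}

# cursor-based reader with fail-closed bounds checks
new_reader <- function(data) {
  env <- new.env(parent = emptyenv())
  env$data <- data; env$pos <- 1L
  env
}
take <- function(rd, n) {
  if (rd$pos + n - 1L > length(rd$data))
    abort_format("truncated input: ran out of bytes while parsing")
  out <- rd$data[rd$pos:(rd$pos + n - 1L)]
  rd$pos <- rd$pos + as.integer(n)
  out
}

#' Deserialize bytes into a weight bundle
#'
#' Inverse of [serialize_weights()]. Rejects bad magic, unsupported versions
#' and truncated input with a format error (distinct from an integrity error);
#' it never returns a partial bundle.
#'
#' @param data raw vector produced by [serialize_weights()].
#' @return a `weight_bundle`.
#' @export
deserialize_weights <- function(data) {
  if (!is.raw(data)) abort_format("expected raw bytes")
  rd <- new_reader(data)
  if (!identical(take(rd, 4L), BUNDLE_MAGIC))
    abort_format("bad magic: not a weight-bundle stream")
  ver <- le_value(take(rd, 2L))
  if (ver != 1) abort_format(sprintf("unsupported bundle version %d", ver))
  n_entries <- le_value(take(rd, 4L))
  entries <- vector("list", n_entries)
  nms <- character(n_entries)
  for (i in seq_len(n_entries)) {
    name_len <- le_value(take(rd, 2L))
    nms[i] <- rawToChar(take(rd, name_len))
    rank <- as.integer(take(rd, 1L))
    d <- vapply(seq_len(rank), function(j) le_value(take(rd, 8L)), 1.0)
    n_vals <- prod(d)
    vals <- readBin(take(rd, 4L * n_vals), "numeric", n = n_vals,
                    size = 4L, endian = "little")
    dim(vals) <- as.integer(d)
    entries[[i]] <- vals
  }
  if (rd$pos != length(data) + 1L)
    abort_format("trailing bytes after last entry")
  names(entries) <- nms
  weight_bundle(entries)
}

#' Exact serialized size of a set of named arrays, in bytes
#'
#' Computes the on-disk size of the bundle encoding from names and shapes
#' alone, without materializing any values. Useful for communication
#' accounting with large architectures.
#'
#' @param names character vector of entry names.
#' @param dims list of integer dimension vectors, parallel to `names`.
#' @return number of bytes.
#' @export
serialized_size_bytes <- function(names, dims) {
  header <- 4 + 2 + 4
  per <- vapply(seq_along(names), function(i) {
    2 + length(charToRaw(enc2utf8(names[i]))) + 1 + 8 * length(dims[[i]]) +
      4 * prod(dims[[i]])
  }, 1.0)
  header + sum(per)
}

#' Write / read a weight bundle file
#' @param bundle a `weight_bundle`.
#' @param path file path.
#' @return `write_bundle_file` returns `path` invisibly; `read_bundle_file`
#'   returns the bundle.
#' @export
write_bundle_file <- function(bundle, path) {
  writeBin(serialize_weights(bundle), path)
  invisible(path)
}

#' @rdname write_bundle_file
#' @export
read_bundle_file <- function(path) {
  deserialize_weights(readBin(path, raw(), n = file.info(path)$size))
}
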