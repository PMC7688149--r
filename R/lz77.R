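#' LZ77 sliding-window compression
#'
#' Greedy longest-match LZ77 with a self-delimiting serialization: a header
#' records the parameter triple (window, min_match, max_match) and the
#' uncompressed length, followed by a flag-bit-prefixed token stream
#' (0 + 8-bit literal, or 1 + fixed-width offset and length fields sized
#' from the header). Decompression therefore takes no parameters.
#' Overlapping matches (offset < length) are produced and honoured, so
#' long runs of one byte code as a literal plus a single match.
#'
#' Defaults follow classic sliding-window practice: window 32768, minimum
#' match 3, maximum match 258.
#'
#' @param data A raw vector or a character scalar (converted with
#'   [charToRaw()]).
#' @param window Sliding-window size in bytes.
#' @param min_match Minimum match length; shorter matches are emitted as
#'   literals.
#' @param max_match Maximum match length.
#' @return `lz77_compress()`: a raw vector holding the serialized stream.
#' @examples
#' x <- charToRaw("AAAAAA")
#' identical(lz77_decompress(lz77_compress(x)), x)
#' @export
lz77_compress <- function(data, window = 32768L, min_match = 3L,
                          max_match = 258L) {
  if (is.character(data)) data <- charToRaw(paste(data, collapse = ""))
  stopifnot(is.raw(data))
  .lz77_compress_raw(data, as.integer(window), as.integer(min_match),
                     as.integer(max_match))
}

#' @rdname lz77_compress
#' @param serialized A raw vector produced by [lz77_compress()].
#' @return `lz77_decompress()`: the original raw vector.
#' @export
lz77_decompress <- function(serialized) {
  stopifnot(is.raw(serialized))
  .lz77_decompress_raw(serialized)
}

#' Inspect the greedy LZ77 token parse
#'
#' Returns the token sequence the compressor emits, without serializing
#' it. Useful for studying the parse and for testing the greedy
#' longest-match property.
#'
#' @inheritParams lz77_compress
#' @return A data.frame with columns `kind` ("literal"/"match"),
#'   `literal` (byte value 0-255 or NA), `offset`, `length`.
#' @export
lz77_tokens <- function(data, window = 32768L, min_match = 3L,
                        max_match = 258L) {
  if (is.character(data)) data <- charToRaw(paste(data, collapse = ""))
  stopifnot(is.raw(data))
  as.data.frame(
    .lz77_tokens_raw(data, as.integer(window), as.integer(min_match),
                     as.integer(max_match)),
    stringsAsFactors = FALSE
  )
}

#' Read the header of a serialized LZ77 stream
#'
#' @param serialized A raw vector produced by [lz77_compress()].
#' @return List with `window`, `min_match`, `max_match`,
#'   `uncompressed_length`.
#' @keywords internal
lz77_header <- function(serialized) {
  stopifnot(is.raw(serialized), length(serialized) >= 20L)
  if (!identical(serialized[1:3], charToRaw("DLZ"))) {
    stop("not an LZ77 stream (bad magic)", call. = FALSE)
  }
  u32 <- function(i) sum(as.integer(serialized[i:(i + 3L)]) * c(1, 256, 65536, 16777216))
  list(window = u32(5L), min_match = u32(9L), max_match = u32(13L),
       uncompressed_length = u32(17L))
}
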