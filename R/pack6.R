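#' Pack a bitstream into printable ASCII by 6-bit groups
#'
#' Consecutive groups of six bits (most-significant-bit first) are read as
#' values 0-63 and emitted as the character with code value + 60, i.e. the
#' range 60-123 (`<` through `{`). The final 0-5 bits do not form a group
#' and are returned as the `remainder`; they travel in the f0 side channel.
#' The offset keeps every payload byte printable and clear of the `#`
#' delimiter (code 35) used by f0.
#'
#' @param bits A bitstring.
#' @return List with `payload` (ASCII string) and `remainder` (bitstring of
#'   length 0-5).
#' @examples
#' pack_bits("100011010111111000011")  # "_St" + remainder "011"
#' @export
pack_bits <- function(bits) {
  b <- .bits(bits)
  n <- length(b)
  k <- n %/% 6L
  payload <- if (k > 0L) {
    m <- matrix(b[seq_len(6L * k)], nrow = 6L)
    vals <- as.integer(crossprod(m, c(32L, 16L, 8L, 4L, 2L, 1L)))
    rawToChar(as.raw(vals + 60L))
  } else ""
  remainder <- if (n > 6L * k) .bitstr(b[(6L * k + 1L):n]) else ""
  list(payload = payload, remainder = remainder)
}

#' Inverse of [pack_bits()]
#'
#' Every payload character expands to exactly six bits (leading zeros
#' preserved); the remainder is appended unchanged.
#'
#' @param payload ASCII string with character codes in 60-123.
#' @param remainder Bitstring of length 0-5.
#' @return The original bitstring.
#' @export
unpack_bits <- function(payload, remainder = "") {
  vals <- as.integer(charToRaw(payload)) - 60L
  if (any(vals < 0L | vals > 63L)) {
    stop("payload character outside code range 60-123", call. = FALSE)
  }
  if (length(vals) == 0L) return(remainder)
  m <- rbind(vals %/% 32L, vals %/% 16L, vals %/% 8L,
             vals %/% 4L, vals %/% 2L, vals) %% 2L
  paste0(.bitstr(as.integer(m)), remainder)
}

#' Assemble the f0 side-channel text
#'
#' f0 carries, `#`-delimited and in fixed order: the five pack remainders
#' (fr1a, fr1b, fr2a, fr2b, fr3), the 4-character rank string, and finally
#' the optional leftover base (possibly empty). There are always exactly
#' six `#` delimiters.
#'
#' @param remainders Character vector of five bitstrings, each 0-5 bits.
#' @param rank A [rank_order()] (or 4-character rank string).
#' @param leftover "" or a single base.
#' @return The f0 string.
#' @examples
#' build_f0(c("011", "0000", "110", "10101", "0"), rank_order("TCAG"))
#' @export
build_f0 <- function(remainders, rank, leftover = "") {
  stopifnot(length(remainders) == 5L, all(nchar(remainders) <= 5L))
  if (!inherits(rank, "rank_order")) rank <- rank_order(rank)
  stopifnot(nchar(leftover) <= 1L)
  paste0(paste(c(remainders, format(rank)), collapse = "#"), "#", leftover)
}

#' Parse the f0 side-channel text
#'
#' Inverse of [build_f0()].
#'
#' @param text f0 string with exactly six `#` delimiters.
#' @return List with `remainders` (five bitstrings), `rank`
#'   (a [rank_order()]) and `leftover`.
#' @export
parse_f0 <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  ch <- .chars(text)
  sep <- which(ch == "#")
  if (length(sep) != 6L) {
    stop("f0 must contain exactly six '#' delimiters, found ",
         length(sep), call. = FALSE)
  }
  bounds <- c(0L, sep, nchar(text) + 1L)
  tokens <- substring(text, bounds[-8L] + 1L, bounds[-1L] - 1L)
  remainders <- tokens[1:5]
  for (r in remainders) {
    if (nchar(r) > 5L) stop("remainder token longer than 5 bits", call. = FALSE)
    .bits(r)  # validates 0/1 content
  }
  rank <- rank_order(tokens[6L])  # validates the permutation
  leftover <- tokens[7L]
  if (nchar(leftover) > 1L || !(leftover %in% c("", "A", "C", "G", "T"))) {
    stop("invalid leftover token: ", leftover, call. = FALSE)
  }
  list(remainders = remainders, rank = rank, leftover = leftover)
}

#' Pack a stage-1 bundle into the six final payloads
#'
#' Applies [pack_bits()] to the five bitstreams and assembles f0 from the
#' remainders, the rank and the leftover base. These six text payloads
#' (f1aa, f1bb, f2aa, f2bb, f3, f0) are what the second-phase LZ77 coder
#' compresses.
#'
#' @param bundle A `stage1_bundle` from [stage1_transform()].
#' @return A `packed_set`: named list of the six payload strings.
#' @export
pack_stage1 <- function(bundle) {
  streams <- c("fr1a", "fr1b", "fr2a", "fr2b", "fr3")
  packed <- lapply(streams, function(nm) pack_bits(bundle[[nm]]))
  payloads <- vapply(packed, `[[`, "", "payload")
  remainders <- vapply(packed, `[[`, "", "remainder")
  structure(
    list(f1aa = payloads[1L], f1bb = payloads[2L], f2aa = payloads[3L],
         f2bb = payloads[4L], f3 = payloads[5L],
         f0 = build_f0(remainders, bundle$rank, bundle$leftover)),
    class = "packed_set"
  )
}

#' Inverse of [pack_stage1()]
#'
#' @param packed A `packed_set` (named list with f1aa, f1bb, f2aa, f2bb,
#'   f3, f0).
#' @return A `stage1_bundle`.
#' @export
unpack_stage1 <- function(packed) {
  meta <- parse_f0(packed$f0)
  payloads <- c(packed$f1aa, packed$f1bb, packed$f2aa, packed$f2bb, packed$f3)
  streams <- mapply(unpack_bits, payloads, meta$remainders, USE.NAMES = FALSE)
  n_x1 <- sum(.bits(streams[1L]) == 1L)  # ones in fr1a = ones in fr1
  n_rest <- nchar(rle_expand(streams[1L], streams[2L])) - n_x1
  structure(
    list(fr1a = streams[1L], fr1b = streams[2L], fr2a = streams[3L],
         fr2b = streams[4L], fr3 = streams[5L], rank = meta$rank,
         leftover = meta$leftover, original_length = n_x1 + n_rest),
    class = "stage1_bundle"
  )
}

#' @export
print.packed_set <- function(x, ...) {
  cat("<packed_set>\n")
  for (nm in c("f1aa", "f1bb", "f2aa", "f2bb", "f3", "f0")) {
    cat(sprintf("  %-4s %4d bytes", nm, nchar(x[[nm]])))
    if (nchar(x[[nm]]) <= 40L) cat("  ", x[[nm]])
    cat("\n")
  }
  invisible(x)
}
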