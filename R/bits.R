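# Internal bitstring helpers.
#
# Public codec functions take and return bitstreams as plain "0"/"1" character
# strings (the intermediate files of the scheme are exactly such strings);
# internally all per-bit work is done on integer vectors.

# "0101" -> c(0L,1L,0L,1L); "" -> integer(0)
.bits <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  if (!nzchar(x)) return(integer(0))
  v <- utf8ToInt(x) - 48L
  if (any(v < 0L | v > 1L)) {
    stop("bitstring contains characters other than 0/1", call. = FALSE)
  }
  v
}

# c(0L,1L) -> "01"; integer(0) -> ""
.bitstr <- function(b) {
  if (length(b) == 0L) return("")
  intToUtf8(b + 48L)
}

# split a character scalar into single characters
.chars <- function(x) {
  if (!nzchar(x)) return(character(0))
  strsplit(x, "", fixed = TRUE)[[1L]]
}
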