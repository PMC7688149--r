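# Shared helpers and independent oracles for the test suite.

`%||%` <- function(a, b) if (is.null(a)) b else a

# All bitstrings of a given length, as strings (enumeration by integer).
all_bitstrings <- function(len) {
  if (len == 0L) return("")
  m <- sapply(seq_len(len), function(b) rep(rep(0:1, each = 2^(len - b)),
                                            length.out = 2^len))
  apply(matrix(as.character(m), ncol = len), 1L, paste, collapse = "")
}

# Independent RLE-halving oracle: literal per-bit walk of the rule.
oracle_rle_halve <- function(fr1) {
  ch <- strsplit(fr1, "")[[1]]
  a <- character(0); b <- character(0)
  i <- 1L
  while (i <= length(ch)) {
    if (ch[i] == "1") {
      a <- c(a, "1"); i <- i + 1L
    } else {
      j <- i
      while (j <= length(ch) && ch[j] == "0") j <- j + 1L
      L <- j - i
      a <- c(a, rep("0", (L + 1L) %/% 2L))
      b <- c(b, as.character(L %% 2L))
      i <- j
    }
  }
  list(fr1a = paste(a, collapse = ""), fr1b = paste(b, collapse = ""))
}

# Independent 6-bit packing oracle via strtoi on explicit groups.
oracle_pack <- function(bits) {
  n <- nchar(bits)
  k <- n %/% 6L
  payload <- ""
  if (k > 0L) {
    groups <- substring(bits, 6L * (seq_len(k) - 1L) + 1L, 6L * seq_len(k))
    payload <- rawToChar(as.raw(strtoi(groups, base = 2L) + 60L))
  }
  list(payload = payload,
       remainder = if (n > 6L * k) substring(bits, 6L * k + 1L, n) else "")
}

# Brute-force longest-match scanner for the greedy LZ77 parse: at each
# position scan every window offset and keep the longest match, taking a
# literal when no match reaches min_match.
oracle_lz77_parse <- function(bytes, window, min_match, max_match) {
  n <- length(bytes)
  kinds <- character(0); lens <- integer(0)
  i <- 1L
  while (i <= n) {
    best <- 0L
    limit <- min(max_match, n - i + 1L)
    if (limit >= min_match) {
      for (off in seq_len(min(window, i - 1L))) {
        len <- 0L
        while (len < limit &&
               bytes[i - off + ((len) %% off)] == bytes[i + len]) {
          # overlapping match: source wraps within the offset period
          len <- len + 1L
        }
        if (len > best) best <- len
        if (best >= limit) break
      }
    }
    if (best >= min_match) {
      kinds <- c(kinds, "match"); lens <- c(lens, best); i <- i + best
    } else {
      kinds <- c(kinds, "literal"); lens <- c(lens, NA_integer_); i <- i + 1L
    }
  }
  data.frame(kind = kinds, length = lens, stringsAsFactors = FALSE)
}

# Random ACGT string helper (composition optionally skewed).
random_dna <- function(n, probs = c(0.25, 0.25, 0.25, 0.25)) {
  if (n == 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = probs),
        collapse = "")
}

# Random string over the non-primary alphabet of a rank.
random_f1 <- function(n, rank) {
  if (n == 0L) return("")
  paste(sample(rank$order[2:4], n, replace = TRUE), collapse = "")
}
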