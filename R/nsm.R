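#' Nour-Sharawi phase-1 three-file splitter
#'
#' The baseline this codec builds on: the sequence is peeled into three
#' binary indicator files. b1 has one bit per residue, 1 at x1 positions;
#' b2 covers the non-x1 residues, 1 at x2; b3 covers the non-x1/x2
#' residues, 1 at x3 (0 = x4). The split is lossless given the rank. Its
#' total bit count beats the flat 2-bit encoding exactly when the top
#' frequency exceeds the sum of the two lowest (the bacterial-skew
#' applicability condition); see [nsm_total_bits()].
#'
#' @param seq A `dna_sequence` or ACGT string.
#' @param rank A [rank_order()]; when `NULL`, computed with
#'   [compute_rank()] defaults (first-1000-residue sample).
#' @return An `nsm_split`: list with bitstrings `b1`, `b2`, `b3` and the
#'   `rank` used.
#' @examples
#' nsm_encode("TTGAACGATAATCCGTATTTGAAAAAAATT")
#' @export
nsm_encode <- function(seq, rank = NULL) {
  residues <- .residues(seq)
  if (is.null(rank)) rank <- compute_rank(residues)
  pos <- match(.chars(residues), rank$order)
  if (anyNA(pos)) stop("invalid residue for the given rank", call. = FALSE)
  rest <- pos[pos > 1L]
  rest2 <- rest[rest > 2L]
  structure(
    list(b1 = .bitstr(as.integer(pos == 1L)),
         b2 = .bitstr(as.integer(rest == 2L)),
         b3 = .bitstr(as.integer(rest2 == 3L)),
         rank = rank),
    class = "nsm_split"
  )
}

#' Inverse of [nsm_encode()]
#'
#' @param split An `nsm_split`.
#' @return The original `dna_sequence`.
#' @export
nsm_decode <- function(split) {
  b1 <- .bits(split$b1); b2 <- .bits(split$b2); b3 <- .bits(split$b3)
  if (sum(b1 == 0L) != length(b2) || sum(b2 == 0L) != length(b3)) {
    stop("inconsistent NSM stream lengths", call. = FALSE)
  }
  ord <- split$rank$order
  lvl3 <- ifelse(b3 == 1L, ord[3L], ord[4L])
  lvl2 <- character(length(b2))
  lvl2[b2 == 1L] <- ord[2L]
  lvl2[b2 == 0L] <- lvl3
  out <- character(length(b1))
  out[b1 == 1L] <- ord[1L]
  out[b1 == 0L] <- lvl2
  dna_sequence(paste(out, collapse = ""), validate = FALSE)
}

#' @export
print.nsm_split <- function(x, ...) {
  cat("<nsm_split> rank", format(x$rank), "\n")
  cat(sprintf("  b1: %d bits (%d ones)\n", nchar(x$b1), sum(.bits(x$b1))))
  cat(sprintf("  b2: %d bits (%d ones)\n", nchar(x$b2), sum(.bits(x$b2))))
  cat(sprintf("  b3: %d bits (%d ones)\n", nchar(x$b3), sum(.bits(x$b3))))
  cat("  total:", nsm_split_bits(x), "bits\n")
  invisible(x)
}

#' Total bits of an [nsm_encode()] split
#'
#' @param split An `nsm_split`.
#' @return Sum of the three stream lengths.
#' @export
nsm_split_bits <- function(split) {
  sum(nchar(c(split$b1, split$b2, split$b3)))
}

#' NSM phase-1 bit total from base counts alone
#'
#' With descending counts c1 >= c2 >= c3 >= c4 summing to n, the three
#' files have n, n - c1 and n - c1 - c2 bits. The total is below the flat
#' 2-bit cost 2n exactly when c1 > c3 + c4.
#'
#' @param counts Four non-negative base counts (any order; sorted
#'   internally).
#' @param n Sequence length; must equal `sum(counts)`.
#' @return Total bit count, a non-negative integer.
#' @examples
#' nsm_total_bits(c(13, 10, 4, 3), 30)  # 54
#' nsm_total_bits(c(9, 8, 7, 6), 30)   # 64
#' @export
nsm_total_bits <- function(counts, n) {
  stopifnot(length(counts) == 4L, all(counts >= 0))
  if (sum(counts) != n) {
    stop("counts sum to ", sum(counts), ", not n = ", n, call. = FALSE)
  }
  c <- sort(as.integer(counts), decreasing = TRUE)
  as.integer(n + (n - c[1L]) + (n - c[1L] - c[2L]))
}

#' Flat 2-bit baseline cost
#'
#' The cost of the trivial fixed-width encoding: two bits per residue.
#'
#' @param n Sequence length.
#' @return `2 * n`.
#' @export
flat_bits <- function(n) 2L * as.integer(n)
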