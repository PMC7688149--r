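#' Base rank order (x1..x4)
#'
#' The codec orders the four bases by descending frequency in a leading
#' sample of the sequence: the most frequent base is x1, then x2, x3, x4.
#' The rank drives every later stage (the x1 indicator split, pair merging
#' and the prefix-free recode), and the rank actually used is stored in the
#' archive's f0 side channel so decompression never re-derives it.
#'
#' @param order Character vector: a permutation of A, C, G, T, most frequent
#'   first. A 4-character string like `"TCAG"` is also accepted.
#' @param counts Optional integer counts aligned with `order`.
#' @param sample_size Number of leading residues the counts were taken from.
#' @return An object of class `rank_order` with fields `order`, `counts`,
#'   `sample_size`.
#' @examples
#' rank_order("TCAG")
#' @export
rank_order <- function(order, counts = NULL, sample_size = NA_integer_) {
  if (is.character(order) && length(order) == 1L && nchar(order) == 4L) {
    order <- .chars(order)
  }
  if (length(order) != 4L || !setequal(order, c("A", "C", "G", "T"))) {
    stop("rank must be a permutation of A, C, G, T", call. = FALSE)
  }
  if (is.null(counts)) counts <- rep(NA_integer_, 4L)
  stopifnot(length(counts) == 4L)
  structure(
    list(order = order, counts = as.integer(counts),
         sample_size = as.integer(sample_size)),
    class = "rank_order"
  )
}

#' @export
print.rank_order <- function(x, ...) {
  cat("<rank_order> ", paste(x$order, collapse = ""), sep = "")
  if (!all(is.na(x$counts))) {
    cat("  counts:", paste(sprintf("%s=%d", x$order, x$counts), collapse = " "))
  }
  if (!is.na(x$sample_size)) cat("  (sample of", x$sample_size, ")")
  cat("\n")
  invisible(x)
}

#' @export
format.rank_order <- function(x, ...) paste(x$order, collapse = "")

#' Compute the descending-frequency rank of the four bases
#'
#' Counts A, C, G, T in the first `sample_size` residues (the whole sequence
#' when shorter) and sorts them in descending order of count. Ties break
#' alphabetically (A < C < G < T) for determinism; because the archive
#' stores the rank it used, the tie-break never affects losslessness. An
#' explicit `override` (e.g. `"TCAG"`) bypasses the sort entirely while
#' still reporting the sample counts.
#'
#' @param seq A `dna_sequence` or plain ACGT string; must be non-empty.
#' @param sample_size Leading-sample size, default 1000.
#' @param override Optional rank permutation to force (string or character
#'   vector).
#' @return A [rank_order()].
#' @examples
#' compute_rank("TTGAACGATAATCCGTATTTGAAAAAAATT")  # A=13 T=10 G=4 C=3 -> ATGC
#' @export
compute_rank <- function(seq, sample_size = 1000L, override = NULL) {
  residues <- .residues(seq)
  n <- nchar(residues)
  if (n == 0L) stop("cannot rank an empty sequence", call. = FALSE)
  stopifnot(sample_size >= 1L)
  m <- min(n, as.integer(sample_size))
  ch <- .chars(substr(residues, 1L, m))
  bases <- c("A", "C", "G", "T")
  counts <- vapply(bases, function(b) sum(ch == b), integer(1))
  if (!is.null(override)) {
    ro <- rank_order(override, sample_size = m)
    ro$counts <- unname(counts[match(ro$order, bases)])
    return(ro)
  }
  # descending count, ties alphabetical (bases is already sorted)
  ord <- order(-counts)
  rank_order(bases[ord], counts = unname(counts[ord]), sample_size = m)
}
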