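#' Stage-1 transform: overview
#'
#' The stage-1 transform turns a DNA sequence into five bitstreams plus a
#' tiny side channel, all defined relative to the base rank x1..x4
#' ([compute_rank()]):
#'
#' 1. **Primary split** — fr1 marks x1 positions (1) vs everything else (0);
#'    the non-x1 residues, in order, form f1.
#' 2. **Run-length halving** — every maximal zero-run of length L in fr1
#'    becomes ceil(L/2) zeros in fr1a plus a parity bit in fr1b
#'    (0 = even L, 1 = odd L); ones copy through.
#' 3. **Pair merging** — consecutive pairs of f1 (an alphabet of x2, x3, x4)
#'    collapse to one character each: an equal pair (a,a) emits a with flag
#'    0 in fr2a; an unequal pair emits the third character with flag 1 in
#'    fr2a plus an order bit in fr2b (0 when the pair is in descending
#'    frequency order, 1 when ascending). An odd trailing character is the
#'    "leftover", carried verbatim in the side channel.
#' 4. **Prefix-free recode** — the merged stream f2 is recoded to fr3 with
#'    the code x2 -> 0, x3 -> 10, x4 -> 11.
#'
#' Each operation below is exposed with its exact inverse; the round trip
#' is the identity for every input.
#'
#' @name stage1
#' @keywords internal
NULL

#' Split a sequence into the x1 indicator stream and the residual
#'
#' @param seq `dna_sequence` or ACGT string.
#' @param rank A [rank_order()] covering the sequence's residues.
#' @return List with `fr1` (bitstring, one bit per residue; 1 where the
#'   residue is x1) and `f1` (string of the non-x1 residues in order).
#' @examples
#' split_primary("TGGACCGTTAATCCTTTTTTGAAGGACCTT", rank_order("TCAG"))
#' @export
split_primary <- function(seq, rank) {
  residues <- .residues(seq)
  ch <- .chars(residues)
  x1 <- rank$order[1L]
  is1 <- ch == x1
  list(fr1 = .bitstr(as.integer(is1)), f1 = paste(ch[!is1], collapse = ""))
}

#' Inverse of [split_primary()]
#'
#' @param fr1 Indicator bitstring.
#' @param f1 Residual residue string; its length must equal the number of
#'   zeros in `fr1`.
#' @param rank The [rank_order()] used for the split.
#' @return A `dna_sequence`.
#' @export
merge_primary <- function(fr1, f1, rank) {
  b <- .bits(fr1)
  rest <- .chars(f1)
  if (sum(b == 0L) != length(rest)) {
    stop("fr1 has ", sum(b == 0L), " zeros but f1 has ", length(rest),
         " characters", call. = FALSE)
  }
  out <- character(length(b))
  out[b == 1L] <- rank$order[1L]
  out[b == 0L] <- rest
  dna_sequence(paste(out, collapse = ""), validate = FALSE)
}

#' Halve the zero-runs of a bitstream
#'
#' Each maximal run of L zeros is replaced by ceil(L/2) zeros in `fr1a`,
#' with one parity bit appended to `fr1b` (0 if L was even, 1 if odd);
#' 1-bits copy through unchanged. `fr1b` therefore has exactly one bit per
#' maximal zero-run.
#'
#' @param fr1 A bitstring.
#' @return List with `fr1a` and `fr1b` bitstrings.
#' @examples
#' rle_halve("100000011001001111110000000011")
#' @export
rle_halve <- function(fr1) {
  b <- .bits(fr1)
  if (length(b) == 0L) return(list(fr1a = "", fr1b = ""))
  r <- rle(b)
  zero <- r$values == 0L
  newlen <- r$lengths
  newlen[zero] <- (r$lengths[zero] + 1L) %/% 2L  # ceil(L/2)
  list(
    fr1a = .bitstr(rep.int(r$values, newlen)),
    fr1b = .bitstr(r$lengths[zero] %% 2L)
  )
}

#' Inverse of [rle_halve()]
#'
#' Each maximal zero-run of length h in `fr1a` expands to 2h zeros when its
#' parity bit is 0, or 2h - 1 zeros when it is 1.
#'
#' @param fr1a Halved bitstring.
#' @param fr1b Parity bitstring, one bit per maximal zero-run of `fr1a`.
#' @return The original bitstring.
#' @export
rle_expand <- function(fr1a, fr1b) {
  a <- .bits(fr1a)
  p <- .bits(fr1b)
  if (length(a) == 0L) {
    if (length(p) != 0L) stop("parity bits with no zero-runs", call. = FALSE)
    return("")
  }
  r <- rle(a)
  zero <- r$values == 0L
  if (sum(zero) != length(p)) {
    stop("fr1a has ", sum(zero), " zero-runs but fr1b has ", length(p),
         " parity bits", call. = FALSE)
  }
  newlen <- r$lengths
  newlen[zero] <- 2L * r$lengths[zero] - p
  .bitstr(rep.int(r$values, newlen))
}

#' Merge consecutive residue pairs of the residual stream
#'
#' `f1` must contain only the non-primary bases x2, x3, x4. Consecutive
#' pairs (a, b) are merged: if a == b the merged character is a and 0 is
#' appended to `fr2a`; if a != b the merged character is the third member
#' of \{x2, x3, x4\} and 1 is appended to `fr2a`, with an order bit in
#' `fr2b` — 0 when a outranks b in frequency (descending pair), 1 when b
#' outranks a (ascending). A trailing unpaired character is returned as
#' `leftover`.
#'
#' @param f1 Residual string over \{x2, x3, x4\}.
#' @param rank The [rank_order()] in force.
#' @return List with `f2` (merged string), `fr2a`, `fr2b` (bitstrings) and
#'   `leftover` ("" or a single base).
#' @examples
#' pair_merge("GGACCGAACCGAAGGACC", rank_order("TCAG"))
#' @export
pair_merge <- function(f1, rank) {
  ch <- .chars(f1)
  pos <- match(ch, rank$order)
  if (any(pos == 1L, na.rm = TRUE) || anyNA(pos)) {
    stop("f1 may only contain the non-primary bases ",
         paste(rank$order[2:4], collapse = ", "), call. = FALSE)
  }
  n <- length(ch)
  k <- n %/% 2L
  leftover <- if (n %% 2L == 1L) ch[n] else ""
  if (k == 0L) return(list(f2 = "", fr2a = "", fr2b = "", leftover = leftover))
  pa <- pos[seq.int(1L, by = 2L, length.out = k)]
  pb <- pos[seq.int(2L, by = 2L, length.out = k)]
  same <- pa == pb
  out <- integer(k)
  out[same] <- pa[same]
  out[!same] <- 9L - pa[!same] - pb[!same]  # the third of positions {2,3,4}
  list(
    f2 = paste(rank$order[out], collapse = ""),
    fr2a = .bitstr(as.integer(!same)),
    # smaller rank position = higher frequency; ascending pair -> 1
    fr2b = .bitstr(as.integer(pa[!same] > pb[!same])),
    leftover = leftover
  )
}

#' Inverse of [pair_merge()]
#'
#' @param f2 Merged string.
#' @param fr2a Same/different flags, one bit per merged character.
#' @param fr2b Order bits, one per 1-flag in `fr2a`.
#' @param rank The [rank_order()] in force.
#' @param leftover "" or the single unpaired trailing base.
#' @return The residual string `f1`.
#' @export
pair_expand <- function(f2, fr2a, fr2b, rank, leftover = "") {
  ch <- .chars(f2)
  fa <- .bits(fr2a)
  fb <- .bits(fr2b)
  if (length(fa) != length(ch)) {
    stop("fr2a must have one bit per f2 character", call. = FALSE)
  }
  if (sum(fa == 1L) != length(fb)) {
    stop("fr2b must have one bit per unequal pair", call. = FALSE)
  }
  pos <- match(ch, rank$order)
  if (any(pos == 1L, na.rm = TRUE) || anyNA(pos)) {
    stop("f2 may only contain the non-primary bases", call. = FALSE)
  }
  k <- length(ch)
  a <- integer(k); b <- integer(k)
  same <- fa == 0L
  a[same] <- pos[same]; b[same] <- pos[same]
  if (any(!same)) {
    third <- pos[!same]
    # the pair is {2,3,4} \ {third}; lo outranks hi in frequency
    lo <- ifelse(third == 2L, 3L, 2L)
    hi <- ifelse(third == 4L, 3L, 4L)
    asc <- fb == 1L
    a[!same] <- ifelse(asc, hi, lo)
    b[!same] <- ifelse(asc, lo, hi)
  }
  out <- character(2L * k)
  if (k > 0L) {
    out[seq.int(1L, by = 2L, length.out = k)] <- rank$order[a]
    out[seq.int(2L, by = 2L, length.out = k)] <- rank$order[b]
  }
  paste(c(out, if (nzchar(leftover)) leftover), collapse = "")
}

#' Recode the merged stream with the prefix-free code
#'
#' x2 -> `0`, x3 -> `10`, x4 -> `11`. The code is prefix-free, so decoding
#' is unambiguous.
#'
#' @param f2 Merged string over \{x2, x3, x4\}.
#' @param rank The [rank_order()] in force.
#' @return Bitstring `fr3`.
#' @examples
#' encode_fr3("GGAACCCCC", rank_order("TCAG"))
#' @export
encode_fr3 <- function(f2, rank) {
  ch <- .chars(f2)
  pos <- match(ch, rank$order)
  if (any(pos == 1L, na.rm = TRUE) || anyNA(pos)) {
    stop("f2 may only contain the non-primary bases", call. = FALSE)
  }
  paste(c("0", "10", "11")[pos - 1L], collapse = "")
}

#' Inverse of [encode_fr3()]
#'
#' Decodes run-by-run: within a maximal run of k ones, pairs `11` decode to
#' x4; an odd final one must pair with a following zero (`10` -> x3); each
#' remaining zero decodes alone to x2.
#'
#' @param fr3 Bitstring; must be a valid concatenation of the codewords
#'   `0`, `10`, `11`.
#' @param rank The [rank_order()] in force.
#' @return The merged string `f2`.
#' @export
decode_fr3 <- function(fr3, rank) {
  b <- .bits(fr3)
  if (length(b) == 0L) return("")
  r <- rle(b)
  x2 <- rank$order[2L]; x3 <- rank$order[3L]; x4 <- rank$order[4L]
  parts <- vector("list", length(r$values))
  pending <- FALSE  # an unpaired 1 awaiting its 0
  for (i in seq_along(r$values)) {
    len <- r$lengths[i]
    if (r$values[i] == 1L) {
      parts[[i]] <- rep.int(x4, len %/% 2L)
      pending <- len %% 2L == 1L
    } else {
      if (pending) {
        parts[[i]] <- c(x3, rep.int(x2, len - 1L))
        pending <- FALSE
      } else {
        parts[[i]] <- rep.int(x2, len)
      }
    }
  }
  if (pending) stop("truncated codeword at end of fr3", call. = FALSE)
  paste(unlist(parts), collapse = "")
}

#' Run the full stage-1 transform
#'
#' Applies [split_primary()], [rle_halve()], [pair_merge()] and
#' [encode_fr3()] in sequence and bundles the five final bitstreams with
#' the rank and leftover base.
#'
#' @param seq `dna_sequence` or ACGT string.
#' @param rank A [rank_order()]; when `NULL`, computed from `seq` with
#'   [compute_rank()] defaults.
#' @return A `stage1_bundle`: list with `fr1a`, `fr1b`, `fr2a`, `fr2b`,
#'   `fr3`, `rank`, `leftover`, `original_length`.
#' @export
stage1_transform <- function(seq, rank = NULL) {
  residues <- .residues(seq)
  if (is.null(rank)) rank <- compute_rank(residues)
  sp <- split_primary(residues, rank)
  h <- rle_halve(sp$fr1)
  pm <- pair_merge(sp$f1, rank)
  fr3 <- encode_fr3(pm$f2, rank)
  structure(
    list(fr1a = h$fr1a, fr1b = h$fr1b, fr2a = pm$fr2a, fr2b = pm$fr2b,
         fr3 = fr3, rank = rank, leftover = pm$leftover,
         original_length = nchar(residues)),
    class = "stage1_bundle"
  )
}

#' Invert the full stage-1 transform
#'
#' @param bundle A `stage1_bundle` as returned by [stage1_transform()].
#' @return The original `dna_sequence`.
#' @export
stage1_reconstruct <- function(bundle) {
  rank <- bundle$rank
  f2 <- decode_fr3(bundle$fr3, rank)
  f1 <- pair_expand(f2, bundle$fr2a, bundle$fr2b, rank, bundle$leftover)
  fr1 <- rle_expand(bundle$fr1a, bundle$fr1b)
  merge_primary(fr1, f1, rank)
}

#' Total stage-1 payload size in bits
#'
#' @param bundle A `stage1_bundle`.
#' @return Sum of the five bitstream lengths.
#' @export
stage1_bits <- function(bundle) {
  sum(nchar(c(bundle$fr1a, bundle$fr1b, bundle$fr2a, bundle$fr2b, bundle$fr3)))
}

#' @export
print.stage1_bundle <- function(x, ...) {
  cat("<stage1_bundle> rank", format(x$rank),
      " original", x$original_length, "bp\n")
  for (nm in c("fr1a", "fr1b", "fr2a", "fr2b", "fr3")) {
    cat(sprintf("  %-5s %d bits\n", nm, nchar(x[[nm]])))
  }
  if (nzchar(x$leftover)) cat("  leftover:", x$leftover, "\n")
  cat("  total:", stage1_bits(x), "bits (flat 2-bit:",
      2L * x$original_length, "bits)\n")
  invisible(x)
}
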