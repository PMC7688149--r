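# Archive container.
#
# Single-file binary layout:
#   magic "DZAR", version byte (1), uint32le record count,
#   then per record: member count byte, then members in order
#   f1aa, f1bb, f2aa, f2bb, f3, f0 [, fesc] [, fhdr]:
#     name length byte, name bytes, uint32le payload length, payload.
# Every member payload is itself a self-delimiting LZ77 stream
# (lz77_compress), so decompression needs no options. fesc carries the
# non-ACGT escape table ("pos:char" lines); fhdr the FASTA description.

.ARCHIVE_MAGIC <- "DZAR"
.ARCHIVE_VERSION <- 1L
.MEMBER_ORDER <- c("f1aa", "f1bb", "f2aa", "f2bb", "f3", "f0")

.write_u32 <- function(con, x) writeBin(as.integer(x), con, size = 4L, endian = "little")
.read_u32 <- function(con) readBin(con, "integer", size = 4L, endian = "little")

# ---- record-level (in-memory) API -----------------------------------------

#' Compress DNA sequences into an in-memory archive
#'
#' Runs the full pipeline on each record — rank, stage-1 transform, 6-bit
#' packing, LZ77 on each of the six payloads — and serializes the members
#' into the single-file archive format. Each record is compressed
#' independently with its own rank. All parameters needed to decompress
#' travel inside the archive (rank and leftover in f0, LZ77 parameters in
#' each member's stream header), so [decompress_archive()] takes no
#' options.
#'
#' @param seqs A `dna_sequence`, a plain string, or a list of either.
#'   Records carrying an `escapes` attribute (from
#'   `read_sequence(on_nonacgt = "escape")`) get a seventh side-channel
#'   member restoring the escaped characters.
#' @param sample_size Leading-sample size for [compute_rank()].
#' @param rank_override Optional rank string (e.g. `"TCAG"`) applied to
#'   every record.
#' @param window,min_match,max_match LZ77 parameters, see
#'   [lz77_compress()].
#' @return A raw vector holding the archive.
#' @seealso [compress_file()] for the file-based interface.
#' @export
compress_archive <- function(seqs, sample_size = 1000L, rank_override = NULL,
                             window = 32768L, min_match = 3L,
                             max_match = 258L) {
  if (inherits(seqs, "dna_sequence") || is.character(seqs)) seqs <- list(seqs)
  con <- rawConnection(raw(0), "wb")
  on.exit(close(con), add = TRUE)
  writeBin(charToRaw(.ARCHIVE_MAGIC), con)
  writeBin(as.raw(.ARCHIVE_VERSION), con)
  .write_u32(con, length(seqs))
  for (seq in seqs) {
    if (!inherits(seq, "dna_sequence")) seq <- dna_sequence(seq)
    members <- .compress_record(seq, sample_size, rank_override,
                                window, min_match, max_match)
    writeBin(as.raw(length(members)), con)
    for (nm in names(members)) {
      writeBin(as.raw(nchar(nm)), con)
      writeBin(charToRaw(nm), con)
      .write_u32(con, length(members[[nm]]))
      writeBin(members[[nm]], con)
    }
  }
  rawConnectionValue(con)
}

.compress_record <- function(seq, sample_size, rank_override,
                             window, min_match, max_match) {
  rank <- if (seq$length == 0L) {
    rank_order("ACGT", counts = rep(0L, 4L), sample_size = 0L)
  } else {
    compute_rank(seq, sample_size = sample_size, override = rank_override)
  }
  packed <- pack_stage1(stage1_transform(seq, rank))
  members <- lapply(packed[.MEMBER_ORDER], function(p) {
    lz77_compress(charToRaw(p), window, min_match, max_match)
  })
  esc <- attr(seq, "escapes")
  if (!is.null(esc) && nrow(esc) > 0L) {
    txt <- paste(sprintf("%d:%s", esc$position, esc$char), collapse = "\n")
    members$fesc <- lz77_compress(charToRaw(txt), window, min_match, max_match)
  }
  if (!is.null(seq$header)) {
    members$fhdr <- lz77_compress(charToRaw(seq$header), window, min_match,
                                  max_match)
  }
  members
}

# Parse the raw archive into per-record member lists (still compressed).
.read_archive <- function(blob) {
  stopifnot(is.raw(blob))
  con <- rawConnection(blob, "rb")
  on.exit(close(con), add = TRUE)
  magic <- rawToChar(readBin(con, "raw", 4L))
  if (!identical(magic, .ARCHIVE_MAGIC)) {
    stop("not a dnalz archive (bad magic)", call. = FALSE)
  }
  version <- as.integer(readBin(con, "raw", 1L))
  if (version != .ARCHIVE_VERSION) {
    stop("unsupported archive version: ", version, call. = FALSE)
  }
  n_rec <- .read_u32(con)
  records <- vector("list", n_rec)
  for (i in seq_len(n_rec)) {
    n_mem <- as.integer(readBin(con, "raw", 1L))
    members <- vector("list", n_mem)
    nms <- character(n_mem)
    for (j in seq_len(n_mem)) {
      nl <- as.integer(readBin(con, "raw", 1L))
      nms[j] <- rawToChar(readBin(con, "raw", nl))
      sz <- .read_u32(con)
      members[[j]] <- readBin(con, "raw", sz)
      if (length(members[[j]]) != sz) {
        stop("truncated archive member: ", nms[j], call. = FALSE)
      }
    }
    names(members) <- nms
    if (!all(.MEMBER_ORDER %in% nms)) {
      stop("archive record ", i, " is missing required members", call. = FALSE)
    }
    records[[i]] <- members
  }
  records
}

#' Decompress an in-memory archive
#'
#' Exact inverse of [compress_archive()].
#'
#' @param blob Raw vector holding the archive.
#' @return A list of `dna_sequence` objects, one per record, with FASTA
#'   headers restored.
#' @export
decompress_archive <- function(blob) {
  lapply(.read_archive(blob), .decompress_record)
}

.decompress_record <- function(members) {
  payloads <- lapply(members[.MEMBER_ORDER],
                     function(m) rawToChar(lz77_decompress(m)))
  bundle <- unpack_stage1(payloads)
  seq <- stage1_reconstruct(bundle)
  if (!is.null(members$fesc)) {
    seq <- .reinsert_escapes(seq, rawToChar(lz77_decompress(members$fesc)))
  }
  if (!is.null(members$fhdr)) {
    seq$header <- rawToChar(lz77_decompress(members$fhdr))
  }
  seq
}

.reinsert_escapes <- function(seq, txt) {
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1L]]
  pos <- as.integer(sub(":.*$", "", lines))
  chr <- sub("^[0-9]+:", "", lines)
  out <- character(seq$length + length(pos))
  out[pos] <- chr
  out[-pos] <- .chars(seq$residues)
  res <- structure(
    list(residues = paste(out, collapse = ""), header = seq$header,
         length = length(out)),
    class = "dna_sequence"
  )
  res
}

# ---- file-level API --------------------------------------------------------

#' Compress a sequence file into a dnalz archive
#'
#' Reads raw text or FASTA, compresses every record independently, writes
#' the archive and returns a summary report. The compression ratio is
#' defined as (uncompressed - compressed) / uncompressed, with the
#' uncompressed size taken as one byte per residue; an empty input reports
#' ratio 0 by convention.
#'
#' @param in_path Input sequence file.
#' @param out_path Archive to write.
#' @param format `"raw"` or `"fasta"`.
#' @param on_nonacgt `"error"` (reject non-ACGT residues, reporting
#'   positions) or `"escape"` (divert them to a side-channel member and
#'   restore them on decompression).
#' @param split Also write the six payloads of the first record as loose
#'   text files `<out_path>.f1aa` etc., mirroring the published layout.
#' @inheritParams compress_archive
#' @return Invisibly, a list with `original_size`, `compressed_size`,
#'   `ratio`, `records` and per-member compressed sizes.
#' @export
compress_file <- function(in_path, out_path, format = c("raw", "fasta"),
                          sample_size = 1000L, rank_override = NULL,
                          window = 32768L, min_match = 3L, max_match = 258L,
                          on_nonacgt = c("error", "escape"), split = FALSE) {
  format <- match.arg(format)
  on_nonacgt <- match.arg(on_nonacgt)
  seqs <- read_sequence(in_path, format = format, on_nonacgt = on_nonacgt)
  blob <- compress_archive(seqs, sample_size = sample_size,
                           rank_override = rank_override, window = window,
                           min_match = min_match, max_match = max_match)
  writeBin(blob, out_path)
  if (split) {
    first <- seqs[[1L]]
    rank <- if (first$length == 0L) rank_order("ACGT") else {
      compute_rank(first, sample_size = sample_size, override = rank_override)
    }
    packed <- pack_stage1(stage1_transform(first, rank))
    for (nm in .MEMBER_ORDER) {
      writeBin(charToRaw(packed[[nm]]), paste0(out_path, ".", nm))
    }
  }
  original <- sum(vapply(seqs, function(s) {
    s$length + nrow(attr(s, "escapes") %||% data.frame())
  }, numeric(1)))
  report <- list(
    original_size = original,
    compressed_size = length(blob),
    ratio = if (original > 0) (original - length(blob)) / original else 0,
    records = length(seqs),
    members = .member_sizes(blob)
  )
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.member_sizes <- function(blob) {
  recs <- .read_archive(blob)
  lapply(recs, function(members) vapply(members, length, integer(1)))
}

#' Decompress a dnalz archive back to sequence file(s)
#'
#' @param in_path Archive written by [compress_file()].
#' @param out_path Output file.
#' @param format `"auto"` (FASTA when the archive holds headers or more
#'   than one record, raw otherwise), `"raw"` (first record only) or
#'   `"fasta"`.
#' @return Invisibly, the list of restored `dna_sequence` objects.
#' @export
decompress_file <- function(in_path, out_path,
                            format = c("auto", "raw", "fasta")) {
  format <- match.arg(format)
  blob <- readBin(in_path, "raw", file.info(in_path)$size)
  seqs <- decompress_archive(blob)
  if (format == "auto") {
    fasta <- length(seqs) > 1L ||
      any(vapply(seqs, function(s) !is.null(s$header), logical(1)))
    format <- if (fasta) "fasta" else "raw"
  }
  if (format == "raw") {
    write_sequence(seqs[[1L]], out_path, format = "raw")
  } else {
    set <- Biostrings::BStringSet(vapply(seqs, `[[`, "", "residues"))
    names(set) <- vapply(seqs, function(s) s$header %||% "", "")
    Biostrings::writeXStringSet(set, out_path)
  }
  invisible(seqs)
}

#' Inspect a dnalz archive
#'
#' @param in_path Archive file.
#' @return A data.frame with one row per member: record, member name,
#'   compressed and uncompressed sizes, and the record's rank and LZ77
#'   window. Printed as a table.
#' @export
inspect_archive <- function(in_path) {
  blob <- readBin(in_path, "raw", file.info(in_path)$size)
  recs <- .read_archive(blob)
  rows <- list()
  for (i in seq_along(recs)) {
    f0 <- rawToChar(lz77_decompress(recs[[i]]$f0))
    rank <- format(parse_f0(f0)$rank)
    for (nm in names(recs[[i]])) {
      hdr <- lz77_header(recs[[i]][[nm]])
      rows[[length(rows) + 1L]] <- data.frame(
        record = i, member = nm,
        compressed = length(recs[[i]][[nm]]),
        uncompressed = hdr$uncompressed_length,
        rank = rank, window = hdr$window,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}
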