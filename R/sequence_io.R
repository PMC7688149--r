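#' DNA sequence objects
#'
#' A `dna_sequence` is a validated, uppercase sequence over the four-letter
#' alphabet `{A, C, G, T}` with an optional free-text header (the FASTA
#' description line). It is the only input type the codec accepts: the
#' stage-1 transform is defined on exactly this alphabet.
#'
#' @param residues Character scalar with the sequence; lowercase is folded to
#'   uppercase and all whitespace is stripped before validation.
#' @param header Optional character scalar (FASTA description) or `NULL`.
#' @param validate If `FALSE`, skip the alphabet check (internal use on
#'   already-validated residues).
#' @return An object of class `dna_sequence` with fields `residues`,
#'   `header` and `length`.
#' @examples
#' s <- dna_sequence("acgtACGT")
#' s$length
#' @export
dna_sequence <- function(residues, header = NULL, validate = TRUE) {
  stopifnot(is.character(residues), length(residues) == 1L)
  residues <- toupper(gsub("\\s+", "", residues))
  if (validate) {
    bad <- which(!(.chars(residues) %in% c("A", "C", "G", "T")))
    if (length(bad) > 0L) {
      show <- utils::head(bad, 10L)
      stop(
        "non-ACGT residue(s) at position(s) ",
        paste(show, collapse = ", "),
        if (length(bad) > length(show)) sprintf(" (and %d more)", length(bad) - length(show)),
        ": ", paste(unique(.chars(residues)[show]), collapse = ", "),
        call. = FALSE
      )
    }
  }
  structure(
    list(residues = residues, header = header, length = nchar(residues)),
    class = "dna_sequence"
  )
}

#' @export
print.dna_sequence <- function(x, ...) {
  cat("<dna_sequence>", x$length, "bp")
  if (!is.null(x$header)) cat("  |", x$header)
  cat("\n")
  if (x$length > 0L) {
    shown <- substr(x$residues, 1L, 60L)
    cat(" ", shown, if (x$length > 60L) "...", "\n")
  }
  invisible(x)
}

#' @export
as.character.dna_sequence <- function(x, ...) x$residues

# Coerce a string or dna_sequence to residue string (no re-validation).
.residues <- function(seq) {
  if (inherits(seq, "dna_sequence")) seq$residues else dna_sequence(seq)$residues
}

#' Read DNA sequences from raw text or FASTA
#'
#' Raw format is a bare sequence, possibly wrapped over several lines; it
#' yields exactly one record with no header. FASTA may hold several records;
#' each becomes its own `dna_sequence` with the description preserved.
#' Lowercase input is folded to uppercase (soft-masking is not retained).
#'
#' By default any character outside `{A,C,G,T}` (including `N` and IUPAC
#' ambiguity codes) aborts with a position report. With
#' `on_nonacgt = "escape"` such characters are instead removed from the
#' residue stream and returned as a `(position, char)` table in the
#' `escapes` attribute of each record, so callers (the archive container)
#' can restore them losslessly.
#'
#' @param path File to read.
#' @param format `"raw"` or `"fasta"`.
#' @param on_nonacgt `"error"` (default) or `"escape"`.
#' @return A list of `dna_sequence` objects (length one for `"raw"`).
#' @seealso [write_sequence()], [compress_file()]
#' @export
read_sequence <- function(path, format = c("raw", "fasta"),
                          on_nonacgt = c("error", "escape")) {
  format <- match.arg(format)
  on_nonacgt <- match.arg(on_nonacgt)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "raw") {
    txt <- paste(readLines(path, warn = FALSE), collapse = "")
    recs <- list(list(residues = txt, header = NULL))
  } else {
    set <- Biostrings::readBStringSet(path)
    recs <- lapply(seq_along(set), function(i) {
      list(residues = as.character(set[[i]]), header = names(set)[i])
    })
  }
  lapply(recs, function(r) .make_record(r$residues, r$header, on_nonacgt))
}

# Normalize, apply the non-ACGT policy, build the dna_sequence.
.make_record <- function(residues, header, on_nonacgt) {
  residues <- toupper(gsub("\\s+", "", residues))
  ch <- .chars(residues)
  bad <- which(!(ch %in% c("A", "C", "G", "T")))
  if (length(bad) == 0L || on_nonacgt == "error") {
    # dna_sequence() raises the position-reporting error itself
    return(dna_sequence(residues, header = header))
  }
  esc <- data.frame(position = bad, char = ch[bad], stringsAsFactors = FALSE)
  seq <- dna_sequence(paste(ch[-bad], collapse = ""), header = header, validate = FALSE)
  attr(seq, "escapes") <- esc
  seq
}

#' Write a DNA sequence to raw text or FASTA
#'
#' Inverse of [read_sequence()]: reading back a written file reproduces the
#' residues exactly.
#'
#' @param seq A `dna_sequence` (or plain string).
#' @param path Output file.
#' @param format `"raw"` or `"fasta"`.
#' @param line_width Residues per line for FASTA (and raw) wrapping.
#' @export
write_sequence <- function(seq, path, format = c("raw", "fasta"),
                           line_width = 70L) {
  format <- match.arg(format)
  stopifnot(line_width >= 1L)
  if (!inherits(seq, "dna_sequence")) seq <- dna_sequence(seq)
  if (format == "raw") {
    writeLines(.wrap_seq(seq$residues, line_width), path)
  } else {
    set <- Biostrings::BStringSet(seq$residues)
    names(set) <- if (is.null(seq$header)) "" else seq$header
    Biostrings::writeXStringSet(set, path, width = line_width)
  }
  invisible(NULL)
}

.wrap_seq <- function(residues, width) {
  n <- nchar(residues)
  if (n == 0L) return("")
  starts <- seq(1L, n, by = width)
  substring(residues, starts, pmin(starts + width - 1L, n))
}
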