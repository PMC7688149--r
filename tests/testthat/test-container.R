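test_that("the worked example survives a full file round trip, rank stored", {
  tmp <- withr::local_tempdir()
  s <- golden_examples()$sequence
  in_path <- file.path(tmp, "seq.txt")
  arc <- file.path(tmp, "seq.dz")
  out <- file.path(tmp, "restored.txt")

  write_sequence(dna_sequence(s), in_path, format = "raw")
  rep <- compress_file(in_path, arc, rank_override = "TCAG")
  expect_identical(rep$records, 1L)
  expect_identical(rep$original_size, 30)
  decompress_file(arc, out)
  expect_identical(read_sequence(out)[[1]]$residues, s)

  info <- inspect_archive(arc)
  expect_setequal(info$member, c("f1aa", "f1bb", "f2aa", "f2bb", "f3", "f0"))
  expect_true(all(info$rank == "TCAG"))
  # f1bb and f2bb payloads are empty in this example
  expect_identical(info$uncompressed[info$member %in% c("f1bb", "f2bb")],
                   c(0, 0))
})

test_that("--split emits the six loose payload files with the published bytes", {
  tmp <- withr::local_tempdir()
  g <- golden_examples()
  in_path <- file.path(tmp, "seq.txt")
  arc <- file.path(tmp, "seq.dz")
  write_sequence(dna_sequence(g$sequence), in_path, format = "raw")
  compress_file(in_path, arc, rank_override = "TCAG", split = TRUE)
  read_payload <- function(ext) {
    p <- paste0(arc, ".", ext)
    rawToChar(readBin(p, "raw", file.info(p)$size))
  }
  expect_identical(read_payload("f1aa"), "_St")
  expect_identical(read_payload("f1bb"), "")
  expect_identical(read_payload("f2aa"), "U")
  expect_identical(read_payload("f2bb"), "")
  expect_identical(read_payload("f3"), "z\\")
  expect_identical(read_payload("f0"), g$inconsistent$f0$rule_derived)
})

test_that("empty sequences and homopolymers produce valid archives", {
  blob <- compress_archive("")
  expect_identical(decompress_archive(blob)[[1]]$residues, "")

  tmp <- withr::local_tempdir()
  in_path <- file.path(tmp, "empty.txt")
  writeLines("", in_path)
  rep <- compress_file(in_path, file.path(tmp, "empty.dz"))
  expect_identical(rep$ratio, 0)

  for (b in c("A", "C", "G", "T")) {
    s <- strrep(b, 5000)
    expect_identical(decompress_archive(compress_archive(s))[[1]]$residues, s)
  }
})

test_that("multi-record FASTA archives restore every record and header", {
  tmp <- withr::local_tempdir()
  fa <- file.path(tmp, "in.fa")
  set.seed(61)
  seqs <- c(random_dna(0), random_dna(137), random_dna(2000, c(0.6, 0.1, 0.1, 0.2)))
  writeLines(c(">r1 empty", "",
               ">r2 medium", seqs[2],
               ">r3 skewed", seqs[3]), fa)
  arc <- file.path(tmp, "in.dz")
  rep <- compress_file(fa, arc, format = "fasta")
  expect_identical(rep$records, 3L)
  out <- file.path(tmp, "out.fa")
  decompress_file(arc, out)
  got <- read_sequence(out, format = "fasta")
  expect_identical(vapply(got, function(s) s$residues, ""), seqs)
  expect_identical(got[[3]]$header, "r3 skewed")
})

test_that("non-ACGT input is rejected under strict policy, restored under escape", {
  tmp <- withr::local_tempdir()
  fa <- file.path(tmp, "n.fa")
  writeLines(c(">with ambiguity", "ACGTNNACGTRYACGT"), fa)
  arc <- file.path(tmp, "n.dz")
  expect_error(compress_file(fa, arc, format = "fasta"), "non-ACGT")
  compress_file(fa, arc, format = "fasta", on_nonacgt = "escape")
  got <- decompress_file(arc, file.path(tmp, "n.out.fa"))
  expect_identical(got[[1]]$residues, "ACGTNNACGTRYACGT")
})

test_that("reported ratio matches recomputation from sizes on disk", {
  tmp <- withr::local_tempdir()
  in_path <- file.path(tmp, "big.txt")
  s <- generate_sequence(20000, probs = c(A = 0.9, C = 0.03, G = 0.03, T = 0.04),
                         repeat_fraction = 0.3, seed = 5)
  write_sequence(s, in_path, format = "raw")
  arc <- file.path(tmp, "big.dz")
  rep <- compress_file(in_path, arc)
  expect_identical(rep$compressed_size, as.integer(file.info(arc)$size))
  expect_equal(rep$ratio,
               (rep$original_size - rep$compressed_size) / rep$original_size)
  expect_gt(rep$ratio, 0)
  # archive strictly smaller than a flat 2-bit encoding of the input
  expect_lt(rep$compressed_size, flat_bits(s$length) / 8)
})

test_that("decompress(compress(s)) is the identity across seeds and options", {
  set.seed(67)
  cases <- expand.grid(
    n = c(1, 2, 7, 64, 513),
    skew = c(TRUE, FALSE),
    window = c(256, 32768)
  )
  for (i in seq_len(nrow(cases))) {
    probs <- if (cases$skew[i]) c(0.55, 0.1, 0.05, 0.3) else rep(0.25, 4)
    s <- random_dna(cases$n[i], probs)
    blob <- compress_archive(s, window = cases$window[i])
    expect_identical(decompress_archive(blob)[[1]]$residues, s)
  }
})
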