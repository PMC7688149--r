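test_that("6-bit packing matches the published payloads (MSB first, +60)", {
  g <- golden_examples()
  p <- pack_bits(g$streams$fr1a)
  expect_identical(p$payload, "_St")     # 100011 -> 35 -> '_'
  expect_identical(p$remainder, "011")
  expect_identical(pack_bits(""), list(payload = "", remainder = ""))
  expect_identical(pack_bits("111111")$payload, "{")  # 63 + 60 = 123
  expect_identical(pack_bits(g$streams$fr3)$payload, "z\\")
})

test_that("unpack_bits inverts pack_bits, preserving leading zeros", {
  expect_identical(unpack_bits("_St", "011"), "100011010111111000011")
  expect_identical(unpack_bits("", "0000"), "0000")  # remainder-only stream
  expect_identical(unpack_bits("<", ""), "000000")   # code 60 -> six zeros
  expect_error(unpack_bits(";", ""), "code range")
  expect_error(unpack_bits("}", ""), "code range")

  set.seed(29)
  for (i in 1:200) {
    bits <- paste(sample(c("0", "1"), sample(0:100, 1), replace = TRUE),
                  collapse = "")
    p <- pack_bits(bits)
    expect_identical(p, oracle_pack(bits))
    expect_lte(nchar(p$remainder), 5L)
    expect_identical(unpack_bits(p$payload, p$remainder), bits)
  }
})

test_that("f0 assembles the remainders, rank and leftover in fixed order", {
  g <- golden_examples()
  f0 <- build_f0(c("011", "0000", "110", "10101", "0"), rank_order("TCAG"))
  expect_identical(f0, g$inconsistent$f0$rule_derived)
  expect_identical(build_f0(rep("", 5), "ACGT"), "#####ACGT#")
  expect_identical(build_f0(c("1", "", "", "", "01"), "TCAG", leftover = "G"),
                   "1####01#TCAG#G")
  expect_error(build_f0(c("000000", "", "", "", ""), "ACGT"), "nchar")
})

test_that("parse_f0 inverts build_f0 and accepts the published token layout", {
  # the reference f0 line as printed (including the printed fr2b token)
  got <- parse_f0("011#0000#110#01101#0#TCAG#")
  expect_identical(got$remainders, c("011", "0000", "110", "01101", "0"))
  expect_identical(got$rank$order, c("T", "C", "A", "G"))
  expect_identical(got$leftover, "")

  expect_identical(parse_f0("#####ACGT#")$remainders, rep("", 5))
  expect_identical(parse_f0("#####ACGT#G")$leftover, "G")
  expect_error(parse_f0("1#2#3"), "six")
  expect_error(parse_f0("#####ACGX#"), "permutation")
  expect_error(parse_f0("000000#####ACGT#"), "six|longer")

  set.seed(31)
  for (i in 1:300) {
    rem <- vapply(1:5, function(j) {
      paste(sample(c("0", "1"), sample(0:5, 1), replace = TRUE), collapse = "")
    }, "")
    rank <- rank_order(paste(sample(c("A", "C", "G", "T")), collapse = ""))
    lo <- sample(c("", "A", "C", "G", "T"), 1)
    f0 <- build_f0(rem, rank, lo)
    got <- parse_f0(f0)
    expect_identical(got$remainders, rem)
    expect_identical(got$rank$order, rank$order)
    expect_identical(got$leftover, lo)
  }
})

test_that("pack_stage1/unpack_stage1 round-trip whole bundles", {
  set.seed(37)
  for (i in 1:50) {
    s <- random_dna(sample(c(0:40, 500, 1001), 1),
                    probs = c(0.4, 0.3, 0.2, 0.1))
    r <- if (nchar(s)) compute_rank(s) else rank_order("ACGT")
    bundle <- stage1_transform(s, r)
    packed <- pack_stage1(bundle)
    back <- unpack_stage1(packed)
    expect_identical(back[c("fr1a", "fr1b", "fr2a", "fr2b", "fr3", "leftover")],
                     bundle[c("fr1a", "fr1b", "fr2a", "fr2b", "fr3", "leftover")])
    expect_identical(back$rank$order, r$order)
    expect_identical(back$original_length, nchar(s))
    expect_identical(stage1_reconstruct(back)$residues, s)
  }
})

test_that("payload characters never collide with the f0 delimiter", {
  set.seed(41)
  for (i in 1:20) {
    bits <- paste(sample(c("0", "1"), 120, replace = TRUE), collapse = "")
    codes <- as.integer(charToRaw(pack_bits(bits)$payload))
    expect_true(all(codes >= 60L & codes <= 123L))
  }
})
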