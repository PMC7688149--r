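golden <- golden_examples()
tcag <- rank_order(golden$rank)

test_that("primary split reproduces the published fr1/f1 and hand traces", {
  sp <- split_primary(golden$sequence, tcag)
  expect_identical(sp$fr1, golden$streams$fr1)
  expect_identical(sp$f1, golden$streams$f1)

  expect_identical(split_primary("TTTT", tcag),
                   list(fr1 = "1111", f1 = ""))
  expect_identical(split_primary("ACGT", tcag),
                   list(fr1 = "0001", f1 = "ACG"))
})

test_that("merge_primary inverts split_primary", {
  sp <- split_primary(golden$sequence, tcag)
  expect_identical(merge_primary(sp$fr1, sp$f1, tcag)$residues,
                   golden$sequence)
  expect_identical(merge_primary("1111", "", tcag)$residues, "TTTT")
  expect_error(merge_primary("1010", "A", tcag), "zeros")

  set.seed(7)
  for (i in 1:200) {
    s <- random_dna(sample(0:500, 1), probs = c(0.4, 0.2, 0.2, 0.2))
    r <- if (nchar(s)) compute_rank(s) else tcag
    sp <- split_primary(s, r)
    expect_identical(merge_primary(sp$fr1, sp$f1, r)$residues, s)
  }
})

test_that("zero-run halving follows the parity rule and matches its oracle", {
  h <- rle_halve(golden$streams$fr1)
  expect_identical(h$fr1a, golden$streams$fr1a)
  expect_identical(h$fr1b, golden$streams$fr1b)

  expect_identical(rle_halve("1"), list(fr1a = "1", fr1b = ""))
  # run of 3 is odd: (3+1)/2 = 2 zeros, parity 1
  expect_identical(rle_halve("0001"), list(fr1a = "001", fr1b = "1"))

  set.seed(11)
  for (i in 1:200) {
    x <- paste(sample(c("0", "1"), sample(0:200, 1), replace = TRUE,
                      prob = c(0.7, 0.3)), collapse = "")
    expect_identical(rle_halve(x), oracle_rle_halve(x))
  }
})

test_that("rle_expand inverts rle_halve and validates the parity stream", {
  expect_identical(rle_expand(golden$streams$fr1a, golden$streams$fr1b),
                   golden$streams$fr1)
  expect_identical(rle_expand("1", ""), "1")
  expect_identical(rle_expand("", ""), "")
  expect_error(rle_expand("001", ""), "parity")
  expect_error(rle_expand("1", "0"), "parity")
})

test_that("pair merging reproduces the worked example and the stated rule", {
  pm <- pair_merge(golden$streams$f1, tcag)
  expect_identical(pm$f2, golden$streams$f2)
  expect_identical(pm$fr2a, golden$streams$fr2a)
  expect_identical(pm$leftover, "")
  # the printed fr2b contradicts the order rule; the rule-derived value is
  # asserted (pairs AC,CG,GA,AG,GA under C>A>G)
  expect_identical(pm$fr2b, golden$inconsistent$fr2b$rule_derived)

  # "AT is converted to G, write 0" under rank CATG
  catg <- rank_order("CATG")
  expect_identical(pair_merge("AT", catg),
                   list(f2 = "G", fr2a = "1", fr2b = "0", leftover = ""))
  expect_identical(pair_merge("AA", catg),
                   list(f2 = "A", fr2a = "0", fr2b = "", leftover = ""))
  # odd length leaves a leftover
  expect_identical(pair_merge("ATG", catg)$leftover, "G")
  # the primary base may not appear
  expect_error(pair_merge("CC", catg), "non-primary")
})

test_that("pair_expand inverts pair_merge", {
  pm <- pair_merge(golden$streams$f1, tcag)
  expect_identical(
    pair_expand(pm$f2, pm$fr2a, pm$fr2b, tcag, pm$leftover),
    golden$streams$f1
  )
  expect_identical(pair_expand("A", "0", "", rank_order("CATG")), "AA")
  expect_error(pair_expand("A", "", "", rank_order("CATG")), "one bit per")

  set.seed(13)
  for (i in 1:500) {
    f1 <- random_f1(sample(0:120, 1), tcag)
    pm <- pair_merge(f1, tcag)
    expect_identical(pair_expand(pm$f2, pm$fr2a, pm$fr2b, tcag, pm$leftover),
                     f1)
  }
})

test_that("the fr3 prefix-free code round-trips and matches the example", {
  expect_identical(encode_fr3(golden$streams$f2, tcag), golden$streams$fr3)
  expect_identical(decode_fr3(golden$streams$fr3, tcag), golden$streams$f2)
  expect_identical(encode_fr3("C", tcag), "0")  # single x2
  expect_identical(decode_fr3("0", tcag), "C")
  expect_error(decode_fr3("1", tcag), "truncated")
  expect_error(decode_fr3("111", tcag), "truncated")

  set.seed(17)
  for (i in 1:500) {
    f2 <- random_f1(sample(0:80, 1), tcag)
    expect_identical(decode_fr3(encode_fr3(f2, tcag), tcag), f2)
  }
})

test_that("fr3 codeword lengths follow the symbol counts", {
  set.seed(19)
  for (i in 1:50) {
    f2 <- random_f1(sample(0:200, 1), tcag)
    ch <- strsplit(f2, "")[[1]]
    n2 <- sum(ch == tcag$order[2])
    expect_identical(nchar(encode_fr3(f2, tcag)),
                     n2 + 2L * (length(ch) - n2))
  }
})

test_that("the full stage-1 transform is invertible across compositions", {
  specs <- list(
    list(n = 0), list(n = 1), list(n = 2), list(n = 3),
    list(n = 1000, probs = c(0.7, 0.1, 0.1, 0.1)),
    list(n = 1000, probs = c(0.25, 0.25, 0.25, 0.25)),
    list(n = 100000, probs = c(0.45, 0.1, 0.1, 0.35))
  )
  for (sp in specs) {
    s <- if (sp$n == 0) "" else
      random_dna(sp$n, probs = sp$probs %||% c(0.25, 0.25, 0.25, 0.25))
    r <- if (nchar(s)) compute_rank(s) else rank_order("ACGT")
    bundle <- stage1_transform(s, r)
    expect_identical(stage1_reconstruct(bundle)$residues, s)
    expect_identical(bundle$original_length, nchar(s))
    # bundle invariants
    expect_identical(sum(strsplit(bundle$fr2a, "")[[1]] == "1"),
                     nchar(bundle$fr2b))
    expect_identical(nzchar(bundle$leftover),
                     (nchar(s) - sum(strsplit(s, "")[[1]] == r$order[1])) %% 2 == 1)
  }
})

test_that("stage-1 size accounting beats the flat 2-bit baseline on skewed input", {
  set.seed(23)
  s <- generate_sequence(20000, probs = c(A = 0.7, C = 0.05, G = 0.05, T = 0.2),
                         seed = 101)
  bundle <- stage1_transform(s)
  expect_lt(stage1_bits(bundle), flat_bits(s$length))
})
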