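test_that("a single substitution gives one (k,k) SNV bubble", {
  # manual k-mer walk: arms {AAC,ACG,CGT} vs {AAT,ATG,TGT}
  g <- build_cdbg("AAACGTTT", "AAATGTTT", 3)
  b <- enumerate_bubbles(g)
  expect_equal(nrow(b), 1L)
  expect_equal(c(b$arm_a, b$arm_b), c(3L, 3L))
  expect_equal(b$category, "SNV")
  expect_equal(c(b$start_a, b$end_a), c(4L, 4L))
  expect_equal(c(b$start_b, b$end_b), c(4L, 4L))
})

test_that("an indel gives one asymmetric AS bubble with a junction region", {
  # arms {AAC,ACG,CGT,GTT} vs {AAT,ATT}
  g <- build_cdbg("AAACGTTT", "AAATTT", 3)
  b <- enumerate_bubbles(g)
  expect_equal(nrow(b), 1L)
  expect_equal(c(b$arm_a, b$arm_b), c(4L, 2L))
  expect_equal(b$category, "AS")
  expect_equal(c(b$start_a, b$end_a), c(4L, 5L)) # the inserted "CG"
  expect_true(b$end_b < b$start_b)               # empty junction interval
  expect_equal(b$start_b, 4L)
})

test_that("identical transcripts produce no bubbles", {
  g <- build_cdbg("AAACGTTT", "AAACGTTT", 3)
  expect_equal(nrow(enumerate_bubbles(g)), 0L)
})

test_that("bubble topology rules follow arm node counts", {
  expect_equal(classify_bubble(3, 3, 3), "SNV")
  expect_equal(classify_bubble(2, 4, 3), "AS")
  expect_equal(classify_bubble(7, 9, 5), "OTHER")
  # combinations outside the three printed rules stay OTHER
  expect_equal(classify_bubble(5, 9, 5), "OTHER")
  expect_equal(classify_bubble(2, 9, 5), "OTHER")
  expect_equal(classify_bubble(c(3, 2), c(3, 4), 3), c("SNV", "AS"))
})

test_that("substitutions at every internal position give (k,k) SNV bubbles", {
  scan <- gen_substitution_scan(60, seed = 8)
  for (i in seq_len(nrow(scan$mutants))) {
    m <- scan$mutants[i, ]
    b <- enumerate_bubbles(build_cdbg(scan$bg, m$seq, m$k))
    expect_equal(nrow(b), 1L)
    expect_equal(c(b$arm_a, b$arm_b), c(m$k, m$k))
    expect_equal(b$category, "SNV")
    expect_equal(c(b$start_a, b$end_a), c(m$pos, m$pos))
  }
})

test_that("clean insertions of length 1..10 give (k-1, k-1+L) AS bubbles", {
  set.seed(9)
  for (L in 1:10) {
    fx <- gen_insertion_pair(L)
    k <- select_k_pair(fx$transcripts$seq[1], fx$transcripts$seq[2], 5)
    b <- enumerate_bubbles(build_cdbg(fx$transcripts$seq[1],
                                      fx$transcripts$seq[2], k))
    expect_equal(nrow(b), 1L)
    expect_equal(b$arm_b, k - 1L)
    expect_equal(b$arm_a, k - 1L + L)
    expect_equal(b$category, "AS")
    # excising the reported region recovers the exclusion transcript
    expect_equal(excise(fx$transcripts$seq[1], b$start_a, b$end_a),
                 fx$transcripts$seq[2])
  }
})
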