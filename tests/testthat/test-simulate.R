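test_that("single-event fixtures satisfy the excision identity", {
  set.seed(60)
  for (type in c("ES", "AA", "AD", "IR")) {
    fx <- gen_event_pair(type)
    expect_equal(excise(fx$transcripts$seq[1], fx$truth$start_a, fx$truth$end_a),
                 fx$transcripts$seq[2])
  }
  # AF/AL/MX: replacing the truth region maps one transcript onto the other
  for (type in c("AF", "AL", "MX")) {
    fx <- gen_event_pair(type)
    t1 <- fx$transcripts$seq[1]
    tr <- fx$truth
    rebuilt <- paste0(substr(fx$transcripts$seq[2], 1, tr$start_b - 1),
                      substr(t1, tr$start_a, tr$end_a),
                      substr(fx$transcripts$seq[2], tr$end_b + 1,
                             nchar(fx$transcripts$seq[2])))
    expect_equal(rebuilt, t1)
  }
})

test_that("intron-derived regions carry the canonical boundary dinucleotides", {
  fx <- gen_event_pair("IR", seed = 61)
  region <- substr(fx$transcripts$seq[1], fx$truth$start_a, fx$truth$end_a)
  expect_equal(substr(region, 1, 2), "GT")
  expect_equal(substr(region, 59, 60), "AG")
  aa <- gen_event_pair("AA", seed = 61)
  expect_equal(substr(aa$transcripts$seq[1], aa$truth$start_a,
                      aa$truth$start_a + 1), "GT")
  ad <- gen_event_pair("AD", seed = 61)
  expect_equal(substr(ad$transcripts$seq[1], ad$truth$end_a - 1,
                      ad$truth$end_a), "AG")
})

test_that("generation is deterministic under a seed", {
  f1 <- gen_event_pair("MX", seed = 62)
  f2 <- gen_event_pair("MX", seed = 62)
  expect_identical(f1, f2)
  d1 <- gen_dataset(n_per_type = 2, seed = 63)
  d2 <- gen_dataset(n_per_type = 2, seed = 63)
  expect_identical(d1, d2)
})

test_that("paralog fixtures differ at exactly the planted positions", {
  fx <- gen_event_pair("SNV_paralog", n_snv = 3, seed = 64)
  mm <- mismatch_positions(fx$transcripts$seq[1], fx$transcripts$seq[2])
  expect_length(mm, 3L)
  expect_equal(mm, as.integer(strsplit(fx$truth$snv_pos, ",")[[1]]))
  expect_true(all(diff(mm) >= 30))
  # the planted count is what the graph pipeline counts
  g <- build_cdbg(fx$transcripts$seq[1], fx$transcripts$seq[2])
  expect_equal(count_snv_bubbles(enumerate_bubbles(g)), 3L)
})

test_that("long-read corruption respects rates, guards and seeds", {
  fx <- gen_event_pair("ES", seed = 65)
  s <- fx$transcripts$seq[1]
  expect_identical(corrupt_tgs(s, 0, 0, seed = 1)$seq, s)
  c1 <- corrupt_tgs(s, 0.01, 0.005, seed = 2, protect = c(121, 180))
  c2 <- corrupt_tgs(s, 0.01, 0.005, seed = 2, protect = c(121, 180))
  expect_identical(c1, c2)
  if (nrow(c1$errors) > 0) {
    expect_true(all(abs(outer(c1$errors$pos, c(121, 180), "-")) > 20))
    expect_true(all(c1$errors$len %in% 1:2))
  }
})

test_that("datasets have the advertised shape and files", {
  dir <- withr::local_tempdir()
  ds <- gen_dataset(n_per_type = 2, seed = 66, dir = dir)
  expect_equal(nrow(ds$transcripts), 7L * 2L * 2L)
  expect_equal(nrow(ds$truth), 14L)
  expect_true(file.exists(file.path(dir, "transcripts.fasta")))
  expect_true(file.exists(file.path(dir, "truth.tsv")))
  expect_equal(read_fasta(file.path(dir, "transcripts.fasta")), ds$transcripts)
})

test_that("labeled datasets are class-complete and well-formed", {
  lab <- gen_labeled_dataset(n_per_class = 5, seed = 67)
  expect_equal(as.integer(table(lab$labels)), rep(5L, 4))
  expect_equal(nrow(lab$events), 20L)
  expect_true(all(lab$events$event_type == "UNTYPED"))
  expect_true(all(lab$events$id_a %in% lab$transcripts$id))
})
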