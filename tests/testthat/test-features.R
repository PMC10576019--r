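make_event <- function(fx) {
  ev <- identify_events(fx$transcripts)
  expect_equal(nrow(ev), 1L)
  ev
}

test_that("the feature vector has 1982 stable named dimensions", {
  fx <- gen_event_pair("ES", as_length = 90, seed = 30)
  ev <- make_event(fx)
  f <- featurize(ev, fx$transcripts)
  expect_equal(ncol(f) - 1L, 1982L)
  expect_equal(14L * 96L + 2L * 314L + 10L, 1982L)
  # determinism: identical events give identical vectors
  f2 <- featurize(ev, fx$transcripts)
  expect_identical(f, f2)
  # motif list of another size changes the dimension with a warning
  expect_warning(f3 <- featurize(ev, fx$transcripts, motifs = c("GTGAG", "AAA")),
                 "314")
  expect_equal(ncol(f3) - 1L, 14L * 96L + 4L + 10L)
})

test_that("per-window features follow the documented 96-value layout", {
  z <- sequence_features("")
  expect_length(z, 96L)
  expect_true(all(z == 0))

  v <- sequence_features("GTAAAG")
  expect_equal(unname(v["len"]), 6)
  expect_equal(unname(v["len_mod3"]), 1)
  expect_equal(unname(v["end5_GT"]), 1)
  expect_equal(unname(v["end3_AG"]), 1)
  expect_equal(unname(v["mono_A"]), 3 / 6)

  w <- sequence_features("AAAA")
  expect_equal(unname(w["mono_A"]), 1)
  expect_equal(unname(w["di_AA"]), 1)
  expect_equal(unname(w["tri_AAA"]), 1)
  expect_true(all(w[grep("end", names(w))] == 0))
})

test_that("motif flags are exact forward-strand substring matches", {
  motifs <- c("GTGAG", "TTTTT")
  v <- motif_features("AAGTGAGAA", "CCCCC", motifs)
  expect_length(v, 4L)
  expect_equal(unname(v), c(1, 0, 0, 0))
  expect_true(all(motif_features("", "", motifs) == 0))
  # motif equal to the whole window still matches
  expect_equal(unname(motif_features("GTGAG", "", "GTGAG"))[1], 1)
})

test_that("region windows cover both splice sites and truncate at ends", {
  fx <- gen_event_pair("ES", as_length = 90, seed = 31)
  ev <- make_event(fx)
  reg <- extract_regions(ev, fx$transcripts)
  expect_equal(nrow(reg), 14L)
  win <- setNames(reg$seq, reg$window)
  expect_equal(nchar(win[["incl_as"]]), 90L)
  expect_equal(win[["excl_as"]], "")
  expect_equal(nchar(win[["incl_up_l"]]), 50L)

  # IR: the donor GT sits at the center boundary of the left-centered window
  ir <- gen_event_pair("IR", seed = 32)
  evi <- make_event(ir)
  regi <- extract_regions(evi, ir$transcripts)
  ctr <- regi$seq[regi$window == "incl_ctr_l"]
  expect_equal(substr(ctr, 26, 27), "GT")

  # event at the very start of the transcript: upstream windows are empty
  af <- gen_event_pair("AF", seed = 33)
  eva <- identify_events(af$transcripts)
  rega <- extract_regions(eva[1, ], af$transcripts)
  expect_equal(rega$seq[rega$window == "incl_up_l"], "")
})

test_that("featurize never reads outside transcript bounds", {
  set.seed(34)
  for (type in c("AF", "AL", "ES")) {
    fx <- gen_event_pair(type)
    ev <- identify_events(fx$transcripts)
    f <- featurize(ev, fx$transcripts)
    vals <- as.matrix(f[, -1])
    freq <- vals[, grep("mono_|di_|tri_|gc_", colnames(vals))]
    expect_true(all(freq >= 0 & freq <= 1))
    flags <- vals[, grep("end5_|end3_|mod3", colnames(vals))]
    expect_true(all(flags %in% c(0, 1)))
  }
})

test_that("typical event vectors are mostly zeros", {
  fx <- gen_event_pair("IR", seed = 35)
  ev <- make_event(fx)
  f <- featurize(ev, fx$transcripts)
  expect_gte(mean(as.matrix(f[, -1]) == 0), 0.6)
})

test_that("event-level block summarizes region composition and position", {
  fx <- gen_event_pair("ES", seed = 36)
  ev <- make_event(fx)
  reg <- extract_regions(ev, fx$transcripts)
  ef <- event_features(reg, default_motifs())
  expect_length(ef, 10L)
  expect_equal(unname(ef["evt_as_len"]), 60)
  expect_equal(unname(ef["evt_rel_start"]), 121 / 300)
  expect_equal(unname(ef["evt_rel_end"]), 180 / 300)
  expect_true(ef["evt_gc_as"] >= 0 && ef["evt_gc_as"] <= 1)
})
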