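analyze_fx <- function(fx, config = as_config()) {
  dbgsplice:::analyze_pair(fx$transcripts$seq[1], fx$transcripts$seq[2],
                           fx$transcripts$id[1], fx$transcripts$id[2], config)
}

test_that("AF/AL/MX are typed by sentinel adjacency with exact regions", {
  for (type in c("AF", "AL", "MX")) {
    fx <- gen_event_pair(type, seed = 20)
    ev <- analyze_fx(fx)
    expect_equal(nrow(ev), 1L)
    expect_equal(ev$event_type, type)
    expect_equal(ev$source, "graph_rule")
    expect_equal(ev[, c("start_a", "end_a", "start_b", "end_b")],
                 fx$truth[, c("start_a", "end_a", "start_b", "end_b")],
                 ignore_attr = TRUE)
  }
})

test_that("the 30% arm rule suppresses AF calls with long alternative exons", {
  # the shorter transcript's arm spans well over 30% of its length
  fx <- gen_event_pair("AF", alt_lengths = c(200L, 190L), shared_length = 100L,
                       seed = 21)
  ev <- analyze_fx(fx)
  expect_false(any(ev$event_type == "AF"))
})

test_that("mirroring a fixture 5' to 3' maps AF calls onto AL calls", {
  fx <- gen_event_pair("AF", seed = 22)
  ev <- analyze_fx(fx)
  expect_equal(ev$event_type, "AF")
  rev_str <- function(s) {
    paste(rev(strsplit(s, "")[[1]]), collapse = "")
  }
  mirrored <- fx
  mirrored$transcripts$seq <- vapply(fx$transcripts$seq, rev_str, character(1))
  ev_m <- analyze_fx(mirrored)
  expect_equal(ev_m$event_type, "AL")
  len_a <- nchar(fx$transcripts$seq[1])
  expect_equal(ev_m$start_a, len_a - ev$end_a + 1L)
  expect_equal(ev_m$end_a, len_a - ev$start_a + 1L)
})

test_that("SNV tolerance separates splicing from paralogy by seqtype", {
  fx <- gen_event_pair("ES", n_snv = 3, seed = 23)
  expect_equal(nrow(analyze_fx(fx, as_config("assembly"))), 0L)
  ev <- analyze_fx(fx, as_config("isoseq"))
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$n_snv, 3L)
  # pure paralog pairs are never called in either mode
  par <- gen_event_pair("SNV_paralog", n_snv = 3, seed = 24)
  expect_equal(nrow(analyze_fx(par, as_config("assembly"))), 0L)
  expect_equal(nrow(analyze_fx(par, as_config("isoseq"))), 0L)
})

test_that("raising the SNV tolerance never removes called pairs", {
  set.seed(25)
  called <- integer()
  fx <- gen_event_pair("ES", n_snv = 2, seed = 25)
  for (tol in 0:4) {
    cfg <- as_config("assembly", snv_tolerance = tol)
    called <- c(called, nrow(analyze_fx(fx, cfg)))
  }
  expect_true(all(diff(called) >= 0))
  expect_equal(called[1], 0L) # 2 SNVs > tolerance 0
  expect_equal(called[5], 1L)
})

test_that("the Iso-Seq gap filter drops 1-2 nt gap bubbles only", {
  bub <- dbgsplice:::empty_bubbles() |>
    dplyr::bind_rows(tibble::tibble(
      i_s = 1L, i_t = 2L, j_s = 1L, j_t = 2L,
      arm_a = c(7L, 7L, 13L, 8L), arm_b = c(8L, 15L, 15L, 8L), k = 8L,
      start_a = 1L, end_a = 1L, start_b = 1L, end_b = 1L,
      touches_source = FALSE, touches_sink = FALSE,
      category = c("AS", "AS", "OTHER", "SNV")
    ))
  iso <- as_config("isoseq")
  kept <- apply_isoseq_error_filter(bub, iso)
  # (k-1, k) gap dropped; (k-1, k+7) retained; large OTHER retained; SNV kept
  expect_equal(kept$arm_b, c(15L, 15L, 8L))
  # assembly mode: identity
  expect_equal(apply_isoseq_error_filter(bub, as_config("assembly")), bub)
})

test_that("excising the called region reproduces the exclusion transcript", {
  set.seed(26)
  for (type in c("ES", "AA", "AD", "IR")) {
    fx <- gen_event_pair(type)
    ev <- analyze_fx(fx)
    expect_equal(nrow(ev), 1L)
    expect_equal(excise(fx$transcripts$seq[1], ev$start_a, ev$end_a),
                 fx$transcripts$seq[2])
  }
})

test_that("identification runs end to end over a mixed dataset", {
  ds <- gen_dataset(n_per_type = 3, seed = 27)
  ev <- identify_events(ds$transcripts)
  found <- paste(ev$id_a, ev$id_b)
  truth <- paste(ds$truth$id_a, ds$truth$id_b)
  expect_gte(mean(truth %in% found), 0.9)
  expect_equal(identify_events(ds$transcripts[0, ]), ev[0, ])
  # deterministic ordering
  expect_equal(ev, identify_events(ds$transcripts[sample(nrow(ds$transcripts)), ]))
})
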