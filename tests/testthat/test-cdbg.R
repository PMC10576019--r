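test_that("select_k finds the shortest repeat-free word length", {
  # brute force: k=1..3 of ACGTACG all repeat; all 4-mers distinct
  expect_equal(select_k("ACGTACG", 1), 4L)
  expect_equal(select_k("ACGT", 1), 1L)
  expect_equal(select_k("AAAA", 1), 4L)
  expect_error(select_k("ACG", 5), "below k_floor")
  # binary search agrees with a linear scan on random inputs
  set.seed(4)
  for (i in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T"), 40, TRUE), collapse = "")
    linear <- 1L
    while (anyDuplicated(bf_kmer_set(s, linear)) ||
           length(bf_kmer_set(s, linear)) < 40 - linear + 1) {
      linear <- linear + 1L
    }
    expect_equal(select_k(s, 1), linear)
  }
})

test_that("pair k is the maximum over the two transcripts", {
  expect_equal(select_k_pair("ACGTACG", "ACGT", 1), 4L)
  expect_equal(select_k_pair("ACGT", "ACGTACG", 1), 4L)
  expect_equal(select_k_pair("ACGT", "TGCA", 1), 1L)
})

test_that("sentinel padding forces shared source and sink k-mers", {
  expect_equal(pad_sequence("ACG", 2), "QQACGPP")
  for (s in c("A", "ACGT", "TTTT")) {
    p <- pad_sequence(s, 3)
    expect_equal(substr(p, 1, 3), "QQQ")
    expect_equal(substr(p, nchar(p) - 2, nchar(p)), "PPP")
  }
})

test_that("graph construction rejects invalid input", {
  expect_error(build_cdbg("ACGNACGT", "ACGTACGA", 5), "N")
  expect_error(build_cdbg("acgtacgt", "ACGTACGA", 5), "uppercase")
  # k below the cycle-free minimum: repeated real k-mer
  expect_error(build_cdbg("ACGTACG", "TTTTAAAC", 2), "repeated k-mer")
})

test_that("each color path spells its padded transcript exactly", {
  set.seed(5)
  types <- c("ES", "AA", "AD", "IR", "AF", "AL", "MX")
  for (i in 1:40) {
    fx <- gen_event_pair(sample(types, 1), n_snv = sample(0:2, 1))
    g <- build_cdbg(fx$transcripts$seq[1], fx$transcripts$seq[2])
    expect_equal(spell_path(g$path_a, g$k), g$pad_a)
    expect_equal(spell_path(g$path_b, g$k), g$pad_b)
    # acyclicity guarantee: no k-mer repeats within a color path
    expect_equal(anyDuplicated(g$path_a), 0L)
    expect_equal(anyDuplicated(g$path_b), 0L)
  }
})

test_that("the merged two-color graph is a DAG", {
  set.seed(6)
  for (type in c("ES", "AF", "MX")) {
    fx <- gen_event_pair(type)
    g <- build_cdbg(fx$transcripts$seq[1], fx$transcripts$seq[2])
    ig <- igraph::graph_from_data_frame(cdbg_edges(g))
    expect_true(igraph::is_dag(ig))
  }
})

test_that("node table records colors and offsets consistently", {
  g <- build_cdbg("AAACGTTT", "AAATGTTT", 3)
  nodes <- cdbg_nodes(g)
  expect_true(all(nodes$in_a | nodes$in_b))
  shared <- nodes[nodes$in_a & nodes$in_b, ]
  expect_true("QQQ" %in% shared$kmer)
  expect_true("PPP" %in% shared$kmer)
  excl_a <- nodes[nodes$in_a & !nodes$in_b, ]
  expect_setequal(excl_a$kmer, c("AAC", "ACG", "CGT"))
})

test_that("graph export writes DOT and GFA", {
  g <- build_cdbg("AAACGTTT", "AAATGTTT", 3)
  dot <- withr::local_tempfile(fileext = ".dot")
  gfa <- withr::local_tempfile(fileext = ".gfa")
  export_graph(g, dot, "dot")
  export_graph(g, gfa, "gfa")
  expect_match(readLines(dot)[1], "digraph")
  expect_match(readLines(gfa)[1], "^H")
})
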