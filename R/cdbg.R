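#' Smallest cycle-free k for a sequence
#'
#' Returns the smallest `k >= k_floor` such that every length-k substring of
#' `seq` occurs exactly once, i.e. the length of the shortest repeat-free
#' words. A de Bruijn graph of the sequence at this k is guaranteed acyclic
#' with a single walk spelling the sequence. Uniqueness is monotone in k, so
#' the search is a binary search; `nchar(seq)` always qualifies.
#'
#' @param seq DNA string.
#' @param k_floor Smallest k considered (default 5).
#' @return Integer k.
#' @examples
#' select_k("ACGTACG", 1) # 4: every shorter word repeats
#' @export
select_k <- function(seq, k_floor = 5L) {
  n <- nchar(seq)
  k_floor <- as.integer(k_floor)
  if (n < k_floor) {
    rlang::abort(sprintf("sequence length %d is below k_floor %d", n, k_floor))
  }
  if (kmers_unique_at(seq, k_floor)) return(k_floor)
  lo <- k_floor # not unique
  hi <- n       # unique (single substring)
  while (hi - lo > 1L) {
    mid <- (lo + hi) %/% 2L
    if (kmers_unique_at(seq, mid)) hi <- mid else lo <- mid
  }
  hi
}

#' Smallest k that is cycle-free for both transcripts of a pair
#'
#' @param seq_a,seq_b DNA strings.
#' @param k_floor Smallest k considered.
#' @return `max(select_k(seq_a), select_k(seq_b))`.
#' @export
select_k_pair <- function(seq_a, seq_b, k_floor = 5L) {
  max(select_k(seq_a, k_floor), select_k(seq_b, k_floor))
}

#' Pad a sequence with sentinel characters
#'
#' Prepends k copies of `Q` and appends k copies of `P` so that the first
#' k-mer of any padded sequence is `Q^k` and the last is `P^k`: the two
#' transcripts of a pair then share a single source and a single sink node
#' even when their first or last bases differ.
#'
#' @param seq DNA string.
#' @param k k-mer size.
#' @return Padded string.
#' @export
pad_sequence <- function(seq, k) {
  paste0(strrep("Q", k), seq, strrep("P", k))
}

#' Build the colored de Bruijn graph of a transcript pair
#'
#' Nodes are the distinct k-mers of the two sentinel-padded sequences, each
#' carrying the set of colors (transcripts) that contain it; edges connect
#' consecutive k-mer windows. At the k returned by [select_k_pair()] every
#' real k-mer occurs at most once per transcript, so the graph is acyclic and
#' each color traces exactly one source-to-sink path spelling its padded
#' transcript.
#'
#' @param seq_a,seq_b Transcript sequences (uppercase `ACGT`; `N` is rejected).
#' @param k k-mer size, at least the value from [select_k_pair()].
#' @param id_a,id_b Transcript identifiers.
#' @return An object of class `cdbg`.
#' @export
build_cdbg <- function(seq_a, seq_b, k = NULL, id_a = "A", id_b = "B") {
  if (grepl("N", seq_a, fixed = TRUE) || grepl("N", seq_b, fixed = TRUE)) {
    rlang::abort("transcripts containing N are not supported in graph construction")
  }
  if (grepl("[^ACGT]", seq_a) || grepl("[^ACGT]", seq_b)) {
    rlang::abort("sequences must be uppercase DNA over {A,C,G,T}")
  }
  if (is.null(k)) k <- select_k_pair(seq_a, seq_b)
  k <- as.integer(k)
  pad_a <- pad_sequence(seq_a, k)
  pad_b <- pad_sequence(seq_b, k)
  path_a <- seq_kmers(pad_a, k)
  path_b <- seq_kmers(pad_b, k)
  if (anyDuplicated(path_a) || anyDuplicated(path_b)) {
    rlang::abort("repeated k-mer within one padded sequence: k below the cycle-free minimum")
  }
  structure(
    list(
      id_a = id_a, id_b = id_b,
      seq_a = seq_a, seq_b = seq_b,
      k = k, k_set = k,
      pad_a = pad_a, pad_b = pad_b,
      path_a = path_a, path_b = path_b
    ),
    class = "cdbg"
  )
}

#' @export
print.cdbg <- function(x, ...) {
  cat(sprintf("<cdbg> %s (%d nt) vs %s (%d nt), k = %d, %d nodes\n",
              x$id_a, nchar(x$seq_a), x$id_b, nchar(x$seq_b), x$k,
              length(union(x$path_a, x$path_b))))
  invisible(x)
}

#' Node table of a colored de Bruijn graph
#'
#' @param graph A `cdbg` object.
#' @return Tibble with columns `kmer`, `in_a`, `in_b`, `offset_a`, `offset_b`
#'   (0-based start positions in the padded sequences; NA when the color is
#'   absent).
#' @export
cdbg_nodes <- function(graph) {
  kmer <- union(graph$path_a, graph$path_b)
  tibble::tibble(
    kmer = kmer,
    in_a = kmer %in% graph$path_a,
    in_b = kmer %in% graph$path_b,
    offset_a = match(kmer, graph$path_a) - 1L,
    offset_b = match(kmer, graph$path_b) - 1L
  )
}

#' Edge table of a colored de Bruijn graph
#'
#' @param graph A `cdbg` object.
#' @return Tibble with columns `from`, `to` (k-mer labels), deduplicated over
#'   the two color paths.
#' @export
cdbg_edges <- function(graph) {
  e <- function(p) {
    if (length(p) < 2L) {
      return(tibble::tibble(from = character(), to = character()))
    }
    tibble::tibble(from = p[-length(p)], to = p[-1])
  }
  dplyr::distinct(dplyr::bind_rows(e(graph$path_a), graph$path_b |> e()))
}

#' Export a graph for external viewers
#'
#' Writes GraphViz DOT or GFA1 for debugging small graphs.
#'
#' @param graph A `cdbg` object.
#' @param path Output path.
#' @param format `"dot"` or `"gfa"`.
#' @return `path`, invisibly.
#' @export
export_graph <- function(graph, path, format = c("dot", "gfa")) {
  format <- match.arg(format)
  nodes <- cdbg_nodes(graph)
  edges <- cdbg_edges(graph)
  if (format == "dot") {
    col <- ifelse(nodes$in_a & nodes$in_b, "gray",
                  ifelse(nodes$in_a, "steelblue", "firebrick"))
    lines <- c(
      "digraph cdbg {",
      sprintf('  "%s" [color=%s];', nodes$kmer, col),
      sprintf('  "%s" -> "%s";', edges$from, edges$to),
      "}"
    )
  } else {
    lines <- c(
      "H\tVN:Z:1.0",
      sprintf("S\t%s\t%s", nodes$kmer, nodes$kmer),
      sprintf("L\t%s\t+\t%s\t+\t%dM", edges$from, edges$to, graph$k - 1L)
    )
  }
  writeLines(lines, path)
  invisible(path)
}

# Longest strictly increasing subsequence; returns indices into x.
# x must contain distinct values (shared k-mers occur once per path).
lis_indices <- function(x) {
  n <- length(x)
  if (n == 0L) return(integer())
  piles_val <- rep(NA_integer_, n)
  piles_idx <- rep(NA_integer_, n)
  prev <- integer(n)
  n_piles <- 0L
  for (i in seq_len(n)) {
    p <- findInterval(x[i] - 1L, piles_val[seq_len(n_piles)]) + 1L
    piles_val[p] <- x[i]
    piles_idx[p] <- i
    prev[i] <- if (p > 1L) piles_idx[p - 1L] else 0L
    if (p > n_piles) n_piles <- p
  }
  out <- integer(n_piles)
  cur <- piles_idx[n_piles]
  for (r in n_piles:1) {
    out[r] <- cur
    cur <- prev[cur]
  }
  out
}

empty_bubbles <- function() {
  tibble::tibble(
    i_s = integer(), i_t = integer(), j_s = integer(), j_t = integer(),
    arm_a = integer(), arm_b = integer(), k = integer(),
    start_a = integer(), end_a = integer(),
    start_b = integer(), end_b = integer(),
    touches_source = logical(), touches_sink = logical(),
    category = character()
  )
}

#' Enumerate bubbles of a colored de Bruijn graph
#'
#' Walks the two color paths in lockstep along their chain of shared anchor
#' nodes (the longest order-consistent chain of nodes common to both paths)
#' and emits one bubble per maximal region where the paths traverse disjoint
#' node runs between a shared node `s` and the next shared node `t`. Arm
#' lengths are interior node counts; region coordinates are 1-based inclusive
#' on the unpadded transcripts, with `end < start` encoding an empty region at
#' a junction. Each bubble is classified by [classify_bubble()].
#'
#' @param graph A `cdbg` object.
#' @return Tibble with one row per bubble, ordered by position: anchor path
#'   positions (`i_s`, `i_t`, `j_s`, `j_t`), interior node counts `arm_a`,
#'   `arm_b`, the detection `k`, regions `start_a`/`end_a`/`start_b`/`end_b`,
#'   sentinel adjacency flags and `category` (`SNV`, `AS` or `OTHER`).
#' @export
enumerate_bubbles <- function(graph) {
  pa <- graph$path_a
  pb <- graph$path_b
  shared_a_pos <- which(pa %in% pb)
  if (length(shared_a_pos) == 0L) return(empty_bubbles())
  b_pos <- match(pa[shared_a_pos], pb)
  keep <- lis_indices(b_pos)
  anchors_a <- shared_a_pos[keep]
  anchors_b <- b_pos[keep]
  n_anchor <- length(anchors_a)
  if (n_anchor < 2L) return(empty_bubbles())
  i_s <- anchors_a[-n_anchor]; i_t <- anchors_a[-1]
  j_s <- anchors_b[-n_anchor]; j_t <- anchors_b[-1]
  gap <- (i_t - i_s > 1L) | (j_t - j_s > 1L)
  if (!any(gap)) return(empty_bubbles())
  k <- graph$k
  out <- tibble::tibble(
    i_s = i_s[gap], i_t = i_t[gap], j_s = j_s[gap], j_t = j_t[gap]
  ) |>
    dplyr::mutate(
      arm_a = .data$i_t - .data$i_s - 1L,
      arm_b = .data$j_t - .data$j_s - 1L,
      k = k,
      start_a = .data$i_s, end_a = .data$i_t - 1L - k,
      start_b = .data$j_s, end_b = .data$j_t - 1L - k,
      touches_source = stringr::str_detect(pa[.data$i_s], "Q"),
      touches_sink = stringr::str_detect(pa[.data$i_t], "P"),
      category = classify_bubble(.data$arm_a, .data$arm_b, k)
    )
  out
}

#' Classify a bubble by its arm topology
#'
#' At the graph's k, a single-nucleotide difference produces two arms of
#' exactly k interior nodes; a clean splice junction produces a short arm of
#' k - 1 interior nodes (the k-mers spanning the junction); bubbles whose arms
#' are both longer than k arise from larger-scale differences (alternative
#' first/last exons, mutually exclusive exons, or merged nearby variants) and
#' are categorized `OTHER`. Combinations outside the three rules are also
#' `OTHER` and become refinement candidates rather than being silently called.
#'
#' @param arm_a,arm_b Interior node counts of the two arms.
#' @param k Detection k of the bubble.
#' @return Character vector over `"SNV"`, `"AS"`, `"OTHER"` (vectorized).
#' @examples
#' classify_bubble(3, 3, 3) # SNV
#' classify_bubble(2, 4, 3) # AS
#' classify_bubble(7, 9, 5) # OTHER
#' @export
classify_bubble <- function(arm_a, arm_b, k) {
  dplyr::case_when(
    arm_a == k & arm_b == k ~ "SNV",
    pmin(arm_a, arm_b) == k - 1L ~ "AS",
    TRUE ~ "OTHER"
  )
}

# Arm nucleotide sequences of a bubble: the spelled s -> interior -> t path,
# i.e. the padded substring from anchor s through the end of anchor t.
arm_sequences <- function(graph, bubble) {
  k <- graph$k
  list(
    a = substr(graph$pad_a, bubble$i_s, bubble$i_t + k - 1L),
    b = substr(graph$pad_b, bubble$j_s, bubble$j_t + k - 1L)
  )
}

#' Rebuild an unresolved bubble as a sub-graph at smaller k'
#'
#' Spells the two arm sequences of an `OTHER` bubble, determines the smallest
#' cycle-free k' for them, and, when `k' < k`, rebuilds the pair of arms as a
#' sentinel-padded sub-graph at k'. Nearby variants that were merged into one
#' bubble at k become separate bubbles at k'. Returns `NULL` when the bubble
#' cannot be refined (k' would not decrease, or an arm is shorter than the
#' refinement floor).
#'
#' @param graph A `cdbg` object.
#' @param bubble One bubble row from [enumerate_bubbles()].
#' @param k_floor Refinement k floor (default 3).
#' @return A `cdbg` of the two arm sequences at k', carrying the coordinate
#'   offsets needed to translate sub-bubble regions to full-transcript
#'   coordinates, or `NULL`.
#' @export
refine_bubble <- function(graph, bubble, k_floor = 3L) {
  arms <- arm_sequences(graph, bubble)
  strip_a <- stringr::str_remove_all(arms$a, "^Q+|P+$")
  strip_b <- stringr::str_remove_all(arms$b, "^Q+|P+$")
  n_left_a <- nchar(arms$a) - nchar(stringr::str_remove(arms$a, "^Q+"))
  n_left_b <- nchar(arms$b) - nchar(stringr::str_remove(arms$b, "^Q+"))
  if (nchar(strip_a) < k_floor || nchar(strip_b) < k_floor) return(NULL)
  if (strip_a == strip_b) return(NULL)
  k_prime <- select_k_pair(strip_a, strip_b, k_floor)
  if (k_prime >= bubble$k) return(NULL)
  sub <- build_cdbg(strip_a, strip_b, k_prime,
                    id_a = graph$id_a, id_b = graph$id_b)
  sub$offset_a <- bubble$i_s + n_left_a - 1L - graph$k
  sub$offset_b <- bubble$j_s + n_left_b - 1L - graph$k
  sub
}

#' Incorporate a refined sub-graph into the bubble inventory
#'
#' Replaces an `OTHER` bubble with the bubbles of its sub-graph, translating
#' sub-graph regions into full-transcript coordinates, which realizes the
#' mixed-k graph observationally: spelling and bubble enumeration on the
#' merged inventory equal those of a graph whose refined region uses k'.
#'
#' @param bubbles Bubble tibble of the parent graph.
#' @param bubble_row Row index of the refined bubble within `bubbles`.
#' @param subgraph The sub-graph from [refine_bubble()] (or `NULL` for a
#'   no-op).
#' @return The updated bubble tibble, ordered by position.
#' @export
incorporate_refinement <- function(bubbles, bubble_row, subgraph) {
  if (is.null(subgraph)) return(bubbles)
  sub_bub <- enumerate_bubbles(subgraph) |>
    dplyr::mutate(
      start_a = .data$start_a + subgraph$offset_a,
      end_a = .data$end_a + subgraph$offset_a,
      start_b = .data$start_b + subgraph$offset_b,
      end_b = .data$end_b + subgraph$offset_b,
      i_s = NA_integer_, i_t = NA_integer_,
      j_s = NA_integer_, j_t = NA_integer_,
      touches_source = FALSE, touches_sink = FALSE
    )
  dplyr::bind_rows(bubbles[-bubble_row, ], sub_bub) |>
    dplyr::arrange(.data$start_a)
}

# Refine every OTHER bubble of the inventory once (or recursively up to
# max_depth); returns list(bubbles = tibble, k_set = integer vector).
refine_all_bubbles <- function(graph, bubbles, config, depth = 1L) {
  k_set <- graph$k
  repeat {
    idx <- which(bubbles$category == "OTHER" & !is.na(bubbles$i_s))
    if (length(idx) == 0L) break
    changed <- FALSE
    for (i in idx) {
      sub <- refine_bubble(graph, bubbles[i, ], config$refine_k_floor)
      if (!is.null(sub)) {
        k_set <- union(k_set, sub$k)
        sub_res <- refine_sub(sub, config, depth)
        k_set <- union(k_set, sub_res$k_set)
        bubbles <- dplyr::bind_rows(
          bubbles[-i, ],
          sub_res$bubbles
        ) |> dplyr::arrange(.data$start_a)
        changed <- TRUE
        break
      } else {
        bubbles$i_s[i] <- NA_integer_ # mark unresolvable, stays OTHER
      }
    }
    if (!changed && all(is.na(bubbles$i_s[bubbles$category == "OTHER"]))) break
  }
  list(bubbles = bubbles, k_set = sort(k_set))
}

# Enumerate and (optionally recursively) refine inside a sub-graph, returning
# translated bubbles.
refine_sub <- function(subgraph, config, depth) {
  bub <- enumerate_bubbles(subgraph)
  k_set <- subgraph$k
  if (config$recursive_refine && depth < config$max_refine_depth &&
      any(bub$category == "OTHER")) {
    res <- refine_all_bubbles(subgraph, bub, config, depth + 1L)
    bub <- res$bubbles
    k_set <- union(k_set, res$k_set)
  }
  bub <- bub |>
    dplyr::mutate(
      start_a = .data$start_a + subgraph$offset_a,
      end_a = .data$end_a + subgraph$offset_a,
      start_b = .data$start_b + subgraph$offset_b,
      end_b = .data$end_b + subgraph$offset_b,
      i_s = NA_integer_, i_t = NA_integer_,
      j_s = NA_integer_, j_t = NA_integer_,
      touches_source = FALSE, touches_sink = FALSE
    )
  list(bubbles = bub, k_set = k_set)
}
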