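#' Count SNV-induced bubbles
#'
#' @param bubbles Bubble tibble (post-refinement for final counts), as from
#'   [enumerate_bubbles()].
#' @return Integer count of bubbles with category `SNV`.
#' @export
count_snv_bubbles <- function(bubbles) {
  sum(bubbles$category == "SNV")
}

empty_events <- function() {
  tibble::tibble(
    event_id = character(), id_a = character(), id_b = character(),
    event_type = character(),
    start_a = integer(), end_a = integer(),
    start_b = integer(), end_b = integer(),
    n_snv = integer(), source = character(),
    prob_ES = double(), prob_AA = double(),
    prob_AD = double(), prob_IR = double()
  )
}

event_row <- function(id_a, id_b, type, start_a, end_a, start_b, end_b,
                      n_snv, source) {
  tibble::tibble(
    event_id = make_event_id(id_a, id_b, start_a, end_a),
    id_a = id_a, id_b = id_b, event_type = type,
    start_a = as.integer(start_a), end_a = as.integer(end_a),
    start_b = as.integer(start_b), end_b = as.integer(end_b),
    n_snv = as.integer(n_snv), source = source,
    prob_ES = NA_real_, prob_AA = NA_real_,
    prob_AD = NA_real_, prob_IR = NA_real_
  )
}

# Nucleotides spelled by a bubble arm's interior path, sentinels excluded.
arm_spelled_nt <- function(padded, s, t, k) {
  if (t - s <= 1L) return(0L)
  spell <- substr(padded, s + 1L, t + k - 2L)
  nchar(gsub("[QP]", "", spell))
}

#' Call AF/AL/MX events from the original bubble inventory
#'
#' Alternative first exon, alternative last exon and mutually exclusive exons
#' leave a single large (`OTHER`) bubble in the pre-refinement graph. The call
#' requires (i) exactly one `OTHER` bubble, (ii) the arm belonging to the
#' shorter transcript to span less than `afalmx_arm_fraction` of that
#' transcript's length (in spelled nucleotides, sentinels excluded), and
#' (iii) the pair not to exceed the SNV tolerance. The bubble's position
#' fixes the type: adjacent to the source sentinel it is AF, to the sink
#' sentinel AL, otherwise MX.
#'
#' @param graph A `cdbg` object.
#' @param bubbles Pre-refinement bubble tibble of `graph`.
#' @param config An [as_config()].
#' @return A one-row events tibble, or `NULL` when the criteria fail.
#' @export
call_afalmx <- function(graph, bubbles, config = as_config()) {
  if (count_snv_bubbles(bubbles) > config$snv_tolerance) return(NULL)
  other <- bubbles[bubbles$category == "OTHER", ]
  if (nrow(other) != 1L) return(NULL)
  b <- other[1, ]
  k <- graph$k
  len_a <- nchar(graph$seq_a)
  len_b <- nchar(graph$seq_b)
  if (len_a <= len_b) {
    arm_nt <- arm_spelled_nt(graph$pad_a, b$i_s, b$i_t, k)
    short_len <- len_a
  } else {
    arm_nt <- arm_spelled_nt(graph$pad_b, b$j_s, b$j_t, k)
    short_len <- len_b
  }
  if (arm_nt >= config$afalmx_arm_fraction * short_len) return(NULL)
  type <- if (b$touches_source) "AF" else if (b$touches_sink) "AL" else "MX"
  event_row(graph$id_a, graph$id_b, type,
            b$start_a, b$end_a, b$start_b, b$end_b,
            count_snv_bubbles(bubbles), "graph_rule")
}

#' Call untyped AS events from the final bubble inventory
#'
#' A pair is alternatively spliced when it carries at least one AS-induced
#' bubble and no more than `snv_tolerance` SNV-induced bubbles (pairs above
#' the tolerance are putative paralogs and are rejected). Each AS bubble
#' yields one `UNTYPED` event: the longer arm marks the inclusion transcript
#' and its alternative region; the shorter (k - 1 node) arm maps to an empty
#' junction interval on the exclusion transcript.
#'
#' @param graph A `cdbg` object (identifiers and sequences).
#' @param bubbles Final (post-refinement, post-filter) bubble tibble.
#' @param config An [as_config()].
#' @return Events tibble (possibly empty).
#' @export
call_as_pair <- function(graph, bubbles, config = as_config()) {
  n_snv <- count_snv_bubbles(bubbles)
  if (n_snv > config$snv_tolerance) return(empty_events())
  as_bub <- bubbles[bubbles$category == "AS", ]
  if (nrow(as_bub) == 0L) return(empty_events())
  purrr::pmap_dfr(as_bub, function(...) {
    b <- list(...)
    event_row(graph$id_a, graph$id_b, "UNTYPED",
              b$start_a, b$end_a, b$start_b, b$end_b,
              n_snv, NA_character_)
  })
}

#' Drop bubbles shaped like long-read 1-2 nt gap errors
#'
#' Long-read (Iso-Seq) transcripts carry mostly 1-2 nt gap errors. A clean
#' 1-2 nt gap appears as a bubble whose shorter arm has k - 1 interior nodes
#' and whose longer arm has fewer than k + 2; gaps hitting both transcripts
#' within k of each other merge into one slightly larger bubble whose arms
#' are still both below k + 2 interior nodes. In `isoseq` mode every
#' non-SNV bubble with both arms shorter than k + 2 is therefore discarded
#' before event calling; SNV-shaped bubbles are retained so that they still
#' feed the pair's SNV count (judged against the raised Iso-Seq tolerance).
#' When `graph` is supplied (pre-refinement bubbles), unresolved (`OTHER`)
#' bubbles whose spelled arm sequences differ by an edit distance of at most
#' 4 are also dropped: two 1-2 nt gaps merged across the transcripts explain
#' such a bubble entirely, whereas the arms of genuine AF/AL/MX bubbles are
#' unrelated sequences. Each bubble is judged at its own detection k. In
#' `assembly` mode the filter is the identity.
#'
#' @param bubbles Bubble tibble.
#' @param config An [as_config()].
#' @param graph Optional `cdbg` the bubbles came from, enabling the
#'   arm-similarity check.
#' @return Filtered bubble tibble.
#' @export
apply_isoseq_error_filter <- function(bubbles, config = as_config(),
                                      graph = NULL) {
  if (config$seqtype != "isoseq" || nrow(bubbles) == 0L) return(bubbles)
  long_arm <- pmax(bubbles$arm_a, bubbles$arm_b)
  drop <- bubbles$category != "SNV" & long_arm < bubbles$k + 2L
  if (!is.null(graph)) {
    for (i in which(bubbles$category == "OTHER" & !drop & !is.na(bubbles$i_s))) {
      arms <- arm_sequences(graph, bubbles[i, ])
      strip <- gsub("[QP]", "", c(arms$a, arms$b))
      if (utils::adist(strip[1], strip[2]) <= 4L) drop[i] <- TRUE
    }
  }
  bubbles[!drop, ]
}

# Full per-pair analysis: graph, bubbles, AF/AL/MX, refinement, filters,
# AS calls. Returns an events tibble.
analyze_pair <- function(seq_a, seq_b, id_a, id_b, config = as_config()) {
  k <- select_k_pair(seq_a, seq_b, config$k_floor)
  graph <- build_cdbg(seq_a, seq_b, k, id_a, id_b)
  bubbles <- enumerate_bubbles(graph)
  bubbles <- apply_isoseq_error_filter(bubbles, config, graph)
  events <- empty_events()

  afalmx <- call_afalmx(graph, bubbles, config)
  if (!is.null(afalmx)) {
    events <- dplyr::bind_rows(events, afalmx)
    # the single OTHER bubble is consumed by the AF/AL/MX call
    bubbles <- bubbles[bubbles$category != "OTHER", ]
  } else {
    bubbles <- refine_all_bubbles(graph, bubbles, config)$bubbles
  }
  bubbles <- apply_isoseq_error_filter(bubbles, config)
  events <- dplyr::bind_rows(events, call_as_pair(graph, bubbles, config))
  events
}

#' Identify alternatively spliced transcript pairs
#'
#' End-to-end identification: candidate pairing, per-pair colored de Bruijn
#' graph at a dynamically selected k, bubble enumeration and topology
#' classification, AF/AL/MX calling on the original graph, mixed-k refinement
#' of unresolved bubbles, long-read error filtering, paralog rejection by SNV
#' count, and AS event emission. AF/AL/MX events are fully typed by graph
#' rules; the remaining events are `UNTYPED` and can be typed with
#' [classify_events()].
#'
#' @param transcripts Tibble with columns `id`, `seq` (see [read_fasta()]).
#' @param config An [as_config()].
#' @param pairs Optional pre-computed pair tibble ([candidate_pairs()] or
#'   [pairs_from_blast()]); by default the internal k-mer screen is used.
#' @return Events tibble with one row per event: pair ids (canonical order),
#'   `event_type`, 1-based inclusive regions on both transcripts (`end <
#'   start` encodes an empty junction), the pair's SNV-bubble count and
#'   placeholder classifier probabilities.
#' @examples
#' fx <- gen_event_pair("ES", seed = 1)
#' identify_events(fx$transcripts)
#' @export
identify_events <- function(transcripts, config = as_config(), pairs = NULL) {
  if (nrow(transcripts) < 2L) return(empty_events())
  if (is.null(pairs)) {
    pairs <- candidate_pairs(transcripts, config$screen_k, config$min_shared)
  }
  if (nrow(pairs) == 0L) return(empty_events())
  seq_of <- stats::setNames(transcripts$seq, transcripts$id)
  res <- purrr::pmap_dfr(
    pairs[, c("id_a", "id_b")],
    function(id_a, id_b) {
      analyze_pair(seq_of[[id_a]], seq_of[[id_b]], id_a, id_b, config)
    }
  )
  dplyr::bind_rows(empty_events(), res) |>
    dplyr::arrange(.data$id_a, .data$id_b, .data$start_a)
}
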