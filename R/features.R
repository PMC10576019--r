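BASES <- c("A", "C", "G", "T")
END_DINUCS <- c("GT", "GC", "AT", "AG", "AC")

#' Default splicing-motif list (synthetic placeholder)
#'
#' A 314-entry motif list used by the feature module: a core of canonical
#' splicing regulatory elements (donor/acceptor-proximal elements such as
#' GTGAG and GTAAG, branch-point-like words, Fox/Nova/hnRNP-style binding
#' words) padded with deterministically generated 5-7-mers. The list is a
#' synthetic placeholder with the same size and role as a curated splicing
#' motif collection; users reproducing published models should supply their
#' own curated list via [read_motifs()].
#'
#' @return Character vector of 314 motifs.
#' @export
default_motifs <- function() {
  core <- c(
    "GTGAG", "GTAAG", "GTATG", "GTAAGT", "GTGAGT",
    "TTTCAG", "TACTAAC", "CTAAC", "CTGAC",
    "TGCATG", "GCATG",      # Fox-family element
    "TCATC", "YCAY" = "TCATT", "CCATC",
    "TAGGGT", "TAGGGA",     # hnRNP A1-style silencer words
    "GGGGG", "CCCCC", "TTTTT",
    "GAAGAA", "GARGAR" = "GAAGAG", "TGAAGA",
    "CTCTCT", "TCTCTC", "GGGTGG", "GGTGGG"
  )
  core <- unname(core)
  filler <- withr::with_seed(103L, {
    out <- character(0)
    while (length(unique(c(core, out))) < 314L) {
      len <- sample(5:7, 1L)
      out <- c(out, paste(sample(BASES, len, replace = TRUE), collapse = ""))
    }
    out
  })
  unique(c(core, filler))[1:314]
}

window_names <- function() {
  roles <- c("up_l", "down_l", "up_r", "down_r", "ctr_l", "ctr_r", "as")
  c(paste0("incl_", roles), paste0("excl_", roles))
}

# Which side of an event is the inclusion transcript (carries the longer
# region). Returns "a" or "b".
inclusion_side <- function(event) {
  len_a <- max(event$end_a - event$start_a + 1L, 0L)
  len_b <- max(event$end_b - event$start_b + 1L, 0L)
  if (len_a >= len_b) "a" else "b"
}

# The 14 window strings of one event. seq_incl/seq_excl are the transcript
# sequences; L, R the region bounds on the inclusion transcript; J the
# junction position on the exclusion transcript.
event_windows <- function(seq_incl, seq_excl, L, R, J, flank = 50L) {
  half <- flank %/% 2L
  incl <- c(
    up_l = substr_clip(seq_incl, L - flank, L - 1L),
    down_l = substr_clip(seq_incl, L, L + flank - 1L),
    up_r = substr_clip(seq_incl, R - flank + 1L, R),
    down_r = substr_clip(seq_incl, R + 1L, R + flank),
    ctr_l = substr_clip(seq_incl, L - half, L + half - 1L),
    ctr_r = substr_clip(seq_incl, R - half + 1L, R + half),
    as = substr_clip(seq_incl, L, R)
  )
  excl <- c(
    up_l = substr_clip(seq_excl, J - flank, J - 1L),
    down_l = substr_clip(seq_excl, J, J + flank - 1L),
    up_r = substr_clip(seq_excl, J - flank, J - 1L),
    down_r = substr_clip(seq_excl, J, J + flank - 1L),
    ctr_l = substr_clip(seq_excl, J - half, J + half - 1L),
    ctr_r = substr_clip(seq_excl, J - half + 1L, J + half),
    as = ""
  )
  stats::setNames(c(incl, excl), window_names())
}

#' Extract the region windows of an event
#'
#' For the inclusion transcript with left splice site `L` and right splice
#' site `R`, and the exclusion transcript with junction `J`, emits 7 windows
#' per transcript (14 total, fixed order): 50 nt upstream and downstream of
#' each boundary, 50 nt centered on each boundary, and the full alternative
#' region (empty on the exclusion transcript). Windows are truncated at
#' transcript ends; fully out-of-range windows are empty strings.
#'
#' @param event One event row (see [identify_events()]).
#' @param transcripts Transcript tibble with `id`, `seq`.
#' @return Tibble with columns `window`, `seq` (14 rows) carrying attributes
#'   `L`, `R`, `len_incl` used by [event_features()].
#' @export
extract_regions <- function(event, transcripts) {
  event <- as.list(event)
  seqs <- stats::setNames(transcripts$seq, transcripts$id)
  if (!all(c(event$id_a, event$id_b) %in% names(seqs))) {
    rlang::abort("event references transcripts absent from the transcript table")
  }
  side <- inclusion_side(event)
  if (side == "a") {
    seq_incl <- seqs[[event$id_a]]; seq_excl <- seqs[[event$id_b]]
    L <- event$start_a; R <- event$end_a; J <- event$start_b
  } else {
    seq_incl <- seqs[[event$id_b]]; seq_excl <- seqs[[event$id_a]]
    L <- event$start_b; R <- event$end_b; J <- event$start_a
  }
  if (L < 1L || R > nchar(seq_incl) || L > R) {
    rlang::abort(sprintf("event region [%d, %d] outside transcript bounds", L, R))
  }
  win <- event_windows(seq_incl, seq_excl, L, R, J)
  out <- tibble::tibble(window = names(win), seq = unname(win))
  attr(out, "L") <- L
  attr(out, "R") <- R
  attr(out, "len_incl") <- nchar(seq_incl)
  out
}

seq_feature_names <- function() {
  di <- as.vector(outer(BASES, BASES, paste0))
  tri <- as.vector(outer(di, BASES, paste0))
  c("len", "len_mod3",
    paste0("end5_", END_DINUCS), paste0("end3_", END_DINUCS),
    paste0("mono_", BASES), paste0("di_", di), paste0("tri_", tri))
}

#' Per-window sequence features
#'
#' The 96-value block computed for each window: length; a flag for length
#' divisible by 3; presence flags for GT/GC/AT/AG/AC at the 5' and 3' ends;
#' and mono-, di- and trinucleotide frequencies (4 + 16 + 64). An empty
#' window yields 96 zeros.
#'
#' @param window DNA string (possibly empty).
#' @return Named numeric vector of length 96.
#' @examples
#' sequence_features("GTAAAG")[c("len", "end5_GT", "end3_AG", "mono_A")]
#' @export
sequence_features <- function(window) {
  v <- stats::setNames(numeric(96L), seq_feature_names())
  n <- nchar(window)
  if (is.na(window) || n == 0L) return(v)
  v["len"] <- n
  v["len_mod3"] <- as.numeric(n %% 3L == 0L)
  if (n >= 2L) {
    v[paste0("end5_", END_DINUCS)] <- as.numeric(substr(window, 1L, 2L) == END_DINUCS)
    v[paste0("end3_", END_DINUCS)] <- as.numeric(substr(window, n - 1L, n) == END_DINUCS)
  }
  chars <- strsplit(window, "", fixed = TRUE)[[1]]
  v[paste0("mono_", BASES)] <- tabulate(factor(chars, BASES), 4L) / n
  if (n >= 2L) {
    di <- substring(window, 1:(n - 1L), 2:n)
    v[17:32] <- tabulate(factor(di, sub("di_", "", names(v)[17:32])), 16L) / (n - 1L)
  }
  if (n >= 3L) {
    tri <- substring(window, 1:(n - 2L), 3:n)
    v[33:96] <- tabulate(factor(tri, sub("tri_", "", names(v)[33:96])), 64L) / (n - 2L)
  }
  v
}

#' Motif presence flags in the flanking windows
#'
#' For each motif, a binary flag for exact forward-strand substring presence
#' in the upstream flank and one for the downstream flank.
#'
#' @param up50,down50 Flank sequences.
#' @param motifs Character vector of motifs.
#' @return Named numeric vector of length `2 * length(motifs)`, ordered motif
#'   by motif (up flag, then down flag).
#' @export
motif_features <- function(up50, down50, motifs) {
  up <- as.numeric(stringr::str_detect(up50, stringr::fixed(motifs)))
  dn <- as.numeric(stringr::str_detect(down50, stringr::fixed(motifs)))
  idx <- rep(seq_along(motifs), each = 2L)
  v <- as.vector(rbind(up, dn))
  names(v) <- paste0("m", sprintf("%03d", idx), c("_up", "_down"))
  if (nchar(up50) == 0L) v[seq(1, length(v), 2)] <- 0
  if (nchar(down50) == 0L) v[seq(2, length(v), 2)] <- 0
  v
}

#' Event-level summary features
#'
#' The 10-value block summarizing the event as a whole: alternative-region
#' length and length-mod-3 flag, GC content of the region and both flanks,
#' the region's relative position on the inclusion transcript, and the number
#' of distinct motifs present in the region and each flank.
#'
#' @param regions Region tibble from [extract_regions()].
#' @param motifs Character vector of motifs.
#' @return Named numeric vector of length 10.
#' @export
event_features <- function(regions, motifs) {
  win <- stats::setNames(regions$seq, regions$window)
  as_region <- win[["incl_as"]]
  up <- win[["incl_up_l"]]
  dn <- win[["incl_down_r"]]
  L <- attr(regions, "L")
  R <- attr(regions, "R")
  len_incl <- attr(regions, "len_incl")
  hit_count <- function(s) {
    if (nchar(s) == 0L) return(0)
    sum(stringr::str_detect(s, stringr::fixed(motifs)))
  }
  c(
    evt_as_len = nchar(as_region),
    evt_as_len_mod3 = as.numeric(nchar(as_region) %% 3L == 0L && nchar(as_region) > 0L),
    evt_gc_as = gc_content(as_region),
    evt_gc_up = gc_content(up),
    evt_gc_down = gc_content(dn),
    evt_rel_start = L / len_incl,
    evt_rel_end = R / len_incl,
    evt_motifs_as = hit_count(as_region),
    evt_motifs_up = hit_count(up),
    evt_motifs_down = hit_count(dn)
  )
}

#' Build the feature matrix for a set of events
#'
#' Concatenates, per event, the 96-feature block of each of the 14 region
#' windows (1344 values), the per-motif presence flags in the two flanks
#' (`2 * length(motifs)` values; 628 with the default list), and the 10
#' event-level summary features: 1982 features with the default 314-entry
#' motif list, in a fixed global order with stable names.
#'
#' @param events Events tibble.
#' @param transcripts Transcript tibble.
#' @param motifs Motif list (default [default_motifs()]).
#' @return Tibble with `event_id` and one numeric column per feature.
#' @export
featurize <- function(events, transcripts, motifs = default_motifs()) {
  if (length(motifs) != 314L) {
    rlang::warn(sprintf(
      "motif list has %d entries (default 314): feature dimension will be %d",
      length(motifs), 14L * 96L + 2L * length(motifs) + 10L
    ))
  }
  rows <- purrr::map(seq_len(nrow(events)), function(i) {
    regions <- extract_regions(events[i, ], transcripts)
    win <- stats::setNames(regions$seq, regions$window)
    blocks <- purrr::imap(win, function(s, nm) {
      v <- sequence_features(s)
      names(v) <- paste0(nm, "_", names(v))
      v
    })
    mf <- motif_features(win[["incl_up_l"]], win[["incl_down_r"]], motifs)
    ef <- event_features(regions, motifs)
    c(unlist(unname(blocks)), mf, ef)
  })
  mat <- do.call(rbind, rows)
  colnames(mat) <- names(rows[[1]])
  dplyr::bind_cols(
    tibble::tibble(event_id = events$event_id),
    tibble::as_tibble(mat)
  )
}

#' Hash of a motif list
#'
#' Stored inside trained models so that prediction refuses a silently
#' mismatched motif list.
#'
#' @param motifs Character vector.
#' @return Hash string.
#' @export
motif_hash <- function(motifs) {
  rlang::hash(motifs)
}
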