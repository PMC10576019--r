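#' Read full-length transcripts from a FASTA file
#'
#' Sequences are uppercased and U is mapped to T so that RNA and DNA input are
#' handled uniformly. The transcript id is the header token up to the first
#' whitespace and must be unique within the file.
#'
#' @param path Path to a (multi-)FASTA file.
#' @return A tibble with columns `id` and `seq`, one row per record, in file
#'   order.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">t1", "acgu", ">t2", "TTTT"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("FASTA file not found: ", path))
  }
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    rlang::abort(paste0("FASTA file is empty: ", path))
  }
  ids <- sub("\\s.*$", "", names(set))
  if (any(ids == "")) {
    rlang::abort("FASTA record with an empty id")
  }
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    rlang::abort(paste0("duplicate transcript id(s): ",
                        paste(unique(dup), collapse = ", ")))
  }
  seqs <- chartr("U", "T", toupper(as.character(set)))
  bad <- stringr::str_locate(seqs, "[^ACGTN]")[, "start"]
  if (any(!is.na(bad))) {
    i <- which(!is.na(bad))[1]
    rlang::abort(sprintf(
      "non-IUPAC character '%s' in transcript '%s' at position %d",
      substr(seqs[i], bad[i], bad[i]), ids[i], bad[i]
    ))
  }
  if (any(nchar(seqs) == 0L)) {
    rlang::abort("zero-length sequence in FASTA input")
  }
  n_frac <- stringr::str_count(seqs, "N") / nchar(seqs)
  if (any(n_frac > 0.10)) {
    rlang::warn(sprintf("%d transcript(s) contain more than 10%% N bases",
                        sum(n_frac > 0.10)))
  }
  tibble::tibble(id = unname(ids), seq = unname(seqs))
}

#' Write transcripts to a FASTA file
#'
#' @param transcripts Tibble with columns `id` and `seq`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(transcripts, path) {
  set <- Biostrings::BStringSet(transcripts$seq)
  names(set) <- transcripts$id
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Read pairwise similarity hits in BLAST 12-column tabular format
#'
#' Parses the standard `outfmt 6` dialect (qseqid sseqid pident length
#' mismatch gapopen qstart qend sstart send evalue bitscore), keeps hits at or
#' below the e-value cutoff, drops self-hits, and collapses the two
#' orientations of each unordered pair keeping the smallest e-value.
#'
#' @param path Path to the tabular file.
#' @param evalue_cutoff Maximum e-value retained (default 1e-10).
#' @return A tibble with columns `query_id`, `subject_id`, `evalue`, one row
#'   per unordered pair, with `query_id < subject_id`.
#' @export
read_blast_tab <- function(path, evalue_cutoff = 1e-10) {
  if (!file.exists(path)) {
    rlang::abort(paste0("BLAST tabular file not found: ", path))
  }
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(tibble::tibble(query_id = character(), subject_id = character(),
                          evalue = numeric()))
  }
  fields <- stringr::str_split(lines, "\t")
  n_col <- lengths(fields)
  if (any(n_col != 12L)) {
    rlang::abort(sprintf("malformed BLAST tabular row at line %d: expected 12 columns, got %d",
                         which(n_col != 12L)[1], n_col[n_col != 12L][1]))
  }
  qid <- purrr::map_chr(fields, 1)
  sid <- purrr::map_chr(fields, 2)
  ev <- suppressWarnings(as.numeric(purrr::map_chr(fields, 11)))
  if (any(is.na(ev))) {
    rlang::abort(sprintf("malformed e-value at line %d", which(is.na(ev))[1]))
  }
  tibble::tibble(query_id = qid, subject_id = sid, evalue = ev) |>
    dplyr::filter(.data$evalue <= evalue_cutoff, .data$query_id != .data$subject_id) |>
    dplyr::mutate(
      a = pmin(.data$query_id, .data$subject_id),
      b = pmax(.data$query_id, .data$subject_id)
    ) |>
    dplyr::group_by(.data$a, .data$b) |>
    dplyr::summarise(evalue = min(.data$evalue), .groups = "drop") |>
    dplyr::transmute(query_id = .data$a, subject_id = .data$b, evalue = .data$evalue)
}

#' Write called events to a TSV file
#'
#' Coordinates are 1-based inclusive on the unpadded transcripts. An empty
#' region on the exclusion transcript (a pure junction) is written with
#' `region_start = region_end = junction position` and a region length of 0.
#' Classifier probabilities are written with 4 decimal places; events typed by
#' graph rules (AF/AL/MX) carry NA probabilities.
#'
#' @param events Events tibble as produced by [identify_events()] /
#'   [classify_events()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events_tsv <- function(events, path) {
  out <- tibble::tibble(
    pair_id_a = events$id_a %||% character(),
    pair_id_b = events$id_b %||% character(),
    event_type = events$event_type %||% character(),
    region_start_a = pmin(events$start_a, events$end_a + 1L) %||% integer(),
    region_end_a = pmax(events$end_a, events$start_a) %||% integer(),
    region_len_a = pmax(events$end_a - events$start_a + 1L, 0L) %||% integer(),
    region_start_b = pmin(events$start_b, events$end_b + 1L) %||% integer(),
    region_end_b = pmax(events$end_b, events$start_b) %||% integer(),
    region_len_b = pmax(events$end_b - events$start_b + 1L, 0L) %||% integer(),
    n_snv_bubbles = events$n_snv %||% integer(),
    prob_ES = sprintf("%.4f", events$prob_ES %||% numeric()),
    prob_AA = sprintf("%.4f", events$prob_AA %||% numeric()),
    prob_AD = sprintf("%.4f", events$prob_AD %||% numeric()),
    prob_IR = sprintf("%.4f", events$prob_IR %||% numeric())
  )
  # empty regions: collapse to the junction position on both bounds
  if (nrow(out) > 0) {
    empty_a <- out$region_len_a == 0L
    out$region_end_a[empty_a] <- out$region_start_a[empty_a]
    empty_b <- out$region_len_b == 0L
    out$region_end_b[empty_b] <- out$region_start_b[empty_b]
    out$prob_ES[out$prob_ES == "NA"] <- NA_character_
    out$prob_AA[out$prob_AA == "NA"] <- NA_character_
    out$prob_AD[out$prob_AD == "NA"] <- NA_character_
    out$prob_IR[out$prob_IR == "NA"] <- NA_character_
  }
  readr::write_tsv(out, path, na = "NA")
  invisible(path)
}

#' Read an events TSV written by [write_events_tsv()]
#'
#' @param path Path to the TSV.
#' @return Events tibble in the internal representation (empty regions
#'   restored to `end < start`).
#' @export
read_events_tsv <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE)
  tibble::tibble(
    event_id = make_event_id(raw$pair_id_a, raw$pair_id_b,
                             raw$region_start_a, raw$region_end_a),
    id_a = raw$pair_id_a, id_b = raw$pair_id_b,
    event_type = raw$event_type,
    start_a = as.integer(raw$region_start_a),
    end_a = as.integer(ifelse(raw$region_len_a == 0L,
                              raw$region_start_a - 1L, raw$region_end_a)),
    start_b = as.integer(raw$region_start_b),
    end_b = as.integer(ifelse(raw$region_len_b == 0L,
                              raw$region_start_b - 1L, raw$region_end_b)),
    n_snv = as.integer(raw$n_snv_bubbles),
    source = NA_character_,
    prob_ES = as.numeric(raw$prob_ES), prob_AA = as.numeric(raw$prob_AA),
    prob_AD = as.numeric(raw$prob_AD), prob_IR = as.numeric(raw$prob_IR)
  )
}

#' Read a motif list (one motif per line)
#'
#' @param path Plain-text file, one DNA motif per line, alphabet {A,C,G,T}.
#' @return Character vector of motifs.
#' @export
read_motifs <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("motif file not found: ", path))
  }
  motifs <- toupper(trimws(readLines(path)))
  motifs <- motifs[nzchar(motifs)]
  if (any(grepl("[^ACGT]", motifs))) {
    rlang::abort("motif list contains characters outside {A,C,G,T}")
  }
  motifs
}

#' Read a transcript abundance table
#'
#' @param path TSV with columns `transcript_id` and `abundance` (no header
#'   required; a header row is detected and skipped).
#' @return Tibble with columns `transcript_id`, `abundance`.
#' @export
read_abundance <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("transcript_id", first, fixed = TRUE)
  readr::read_tsv(
    path,
    col_names = c("transcript_id", "abundance"),
    skip = if (has_header) 1L else 0L,
    col_types = readr::cols(
      transcript_id = readr::col_character(),
      abundance = readr::col_double()
    )
  )
}
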