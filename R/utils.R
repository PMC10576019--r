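# Internal helpers shared across modules.

#' All k-mers of a sequence, in order
#' @noRd
seq_kmers <- function(seq, k) {
  n <- nchar(seq)
  if (k > n) return(character())
  substring(seq, 1:(n - k + 1), k:n)
}

#' @noRd
kmers_unique_at <- function(seq, k) {
  anyDuplicated(seq_kmers(seq, k)) == 0L
}

#' Random DNA string
#' @noRd
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' GC content of a sequence; 0 for an empty string
#' @noRd
gc_content <- function(seq) {
  n <- nchar(seq)
  if (is.na(seq) || n == 0L) return(0)
  stringr::str_count(seq, "[GC]") / n
}

#' Clipped substring: empty when the window falls outside [1, nchar(seq)]
#' @noRd
substr_clip <- function(seq, lo, hi) {
  n <- nchar(seq)
  lo <- max(1L, lo)
  hi <- min(n, hi)
  if (hi < lo) return("")
  substr(seq, lo, hi)
}

#' Canonical event identifier used across the events/PSI modules
#' @noRd
make_event_id <- function(id_a, id_b, start_a, end_a) {
  paste(id_a, id_b, start_a, end_a, sep = "|")
}

`%||%` <- function(x, y) if (is.null(x)) y else x
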