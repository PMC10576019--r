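#' Discover candidate transcript pairs by shared k-mer screening
#'
#' All-versus-all replacement for an external aligner: two transcripts become
#' a candidate pair when they share at least `min_shared` distinct
#' `screen_k`-mers. Pairs differing by a handful of splicing events share
#' hundreds of screen k-mers, while unrelated random sequences essentially
#' never reach the threshold.
#'
#' @param transcripts Tibble with columns `id`, `seq`.
#' @param screen_k k-mer size of the screen (default 15, minimum 8).
#' @param min_shared Minimum number of shared distinct k-mers (default 20).
#' @return Tibble with columns `id_a`, `id_b` (canonical order,
#'   `id_a < id_b`), `shared_kmer_count`, `source = "internal"`, sorted by
#'   ids. Fewer than two transcripts give an empty result.
#' @examples
#' tx <- tibble::tibble(id = c("t1", "t2"),
#'                      seq = rep(strrep("ACGTTGCAAC", 10), 2))
#' candidate_pairs(tx)
#' @export
candidate_pairs <- function(transcripts, screen_k = 15L, min_shared = 20L) {
  stopifnot(screen_k >= 8L, min_shared >= 1L)
  empty <- tibble::tibble(
    id_a = character(), id_b = character(),
    shared_kmer_count = integer(), source = character()
  )
  if (nrow(transcripts) < 2L) return(empty)
  km <- transcripts |>
    dplyr::mutate(kmer = purrr::map(.data$seq, \(s) unique(seq_kmers(s, screen_k)))) |>
    dplyr::select("id", "kmer") |>
    tidyr::unnest("kmer")
  if (nrow(km) == 0L) return(empty)
  hits <- dplyr::inner_join(km, km, by = "kmer",
                            relationship = "many-to-many",
                            suffix = c("_a", "_b")) |>
    dplyr::filter(.data$id_a < .data$id_b) |>
    dplyr::count(.data$id_a, .data$id_b, name = "shared_kmer_count") |>
    dplyr::filter(.data$shared_kmer_count >= min_shared) |>
    dplyr::mutate(shared_kmer_count = as.integer(.data$shared_kmer_count),
                  source = "internal") |>
    dplyr::arrange(.data$id_a, .data$id_b)
  hits
}

#' Build candidate pairs from imported BLAST hits
#'
#' @param transcripts Tibble with columns `id`, `seq`.
#' @param blast_rows Tibble from [read_blast_tab()].
#' @return Tibble with the same shape as [candidate_pairs()], with
#'   `source = "blast"` and `shared_kmer_count = NA`.
#' @export
pairs_from_blast <- function(transcripts, blast_rows) {
  ids <- unique(c(blast_rows$query_id, blast_rows$subject_id))
  unknown <- setdiff(ids, transcripts$id)
  if (length(unknown) > 0L) {
    rlang::abort(paste0("BLAST hit references unknown transcript id(s): ",
                        paste(unknown, collapse = ", ")))
  }
  blast_rows |>
    dplyr::transmute(
      id_a = pmin(.data$query_id, .data$subject_id),
      id_b = pmax(.data$query_id, .data$subject_id)
    ) |>
    dplyr::distinct() |>
    dplyr::filter(.data$id_a != .data$id_b) |>
    dplyr::mutate(shared_kmer_count = NA_integer_, source = "blast") |>
    dplyr::arrange(.data$id_a, .data$id_b)
}
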