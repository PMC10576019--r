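# Brute-force oracles, deliberately independent of the package internals.

# distinct k-mers of a sequence, by raw substring extraction
bf_kmer_set <- function(seq, k) {
  n <- nchar(seq)
  if (k > n) return(character())
  unique(vapply(1:(n - k + 1), function(i) substr(seq, i, i + k - 1),
                character(1)))
}

bf_shared_kmer_count <- function(s1, s2, k) {
  length(intersect(bf_kmer_set(s1, k), bf_kmer_set(s2, k)))
}

# remove a 1-based inclusive region from a sequence
excise <- function(seq, start, end) {
  paste0(substr(seq, 1, start - 1), substr(seq, end + 1, nchar(seq)))
}

# positions at which two equal-length sequences differ
mismatch_positions <- function(s1, s2) {
  stopifnot(nchar(s1) == nchar(s2))
  which(strsplit(s1, "")[[1]] != strsplit(s2, "")[[1]])
}

# spell a padded sequence back from its ordered k-mer path
spell_path <- function(path, k) {
  paste0(path[1], paste(substr(path[-1], k, k), collapse = ""))
}

rand_tx <- function(n, len = 100) {
  tibble::tibble(
    id = sprintf("tx%03d", seq_len(n)),
    seq = vapply(seq_len(n), function(i) {
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
    }, character(1))
  )
}
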