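EVENT_TYPES <- c("ES", "AA", "AD", "IR", "AF", "AL", "MX")

# Alternative-region boundary dinucleotides per event class. An intron
# retention carries the complete intron (GT..AG); an alternative acceptor
# region carries the 5' end of the intron (donor GT); an alternative donor
# region carries the 3' end (acceptor AG); a skipped exon is exonic and gets
# neutral boundaries. Type labels always come from construction, not from
# boundary content.
region_boundaries <- function(event_type) {
  switch(event_type,
         IR = c("GT", "AG"),
         AA = c("GT", "TC"),
         AD = c("CA", "AG"),
         c("CA", "TC"))
}

plant_region <- function(event_type, as_length) {
  stopifnot(as_length >= 5L)
  b <- region_boundaries(event_type)
  paste0(b[1], random_dna(as_length - 4L), b[2])
}

# Place isolated substitutions into seq at positions spaced far apart from
# each other, the ends, and any protected positions. Returns list(seq, pos).
plant_substitutions <- function(seq, n_snv, spacing, margin) {
  if (n_snv == 0L) return(list(seq = seq, pos = integer()))
  n <- nchar(seq)
  lo <- margin + 1L
  hi <- n - margin
  span <- hi - lo
  if (span < (n_snv - 1L) * spacing) {
    rlang::abort("sequence too short to plant the requested substitutions")
  }
  pos <- lo + round(seq(0, span, length.out = n_snv))
  chars <- strsplit(seq, "")[[1]]
  for (p in pos) {
    chars[p] <- sample(setdiff(BASES, chars[p]), 1L)
  }
  list(seq = paste(chars, collapse = ""), pos = as.integer(pos))
}

truth_row <- function(id_a, id_b, type, start_a, end_a, start_b, end_b,
                      n_snv, snv_pos = integer()) {
  tibble::tibble(
    id_a = id_a, id_b = id_b, event_type = type,
    start_a = as.integer(start_a), end_a = as.integer(end_a),
    start_b = as.integer(start_b), end_b = as.integer(end_b),
    n_snv = as.integer(n_snv),
    snv_pos = paste(snv_pos, collapse = ",")
  )
}

#' Generate one ground-truthed transcript pair
#'
#' Builds a transcript pair carrying exactly one planted event of the
#' requested type on random exon backgrounds, with canonical boundary
#' dinucleotides on intron-derived alternative regions, optional isolated
#' substitutions (paralog-style SNVs) in the shared exons, and exact truth
#' coordinates. Backgrounds are rejection-sampled until the pair is
#' repeat-free at a small k (so graph oracles stay exact) and until the
#' bases adjacent to each junction differ (so the region coordinates are
#' unambiguous).
#'
#' For internal events (ES/AA/AD/IR) the first transcript includes the
#' alternative region and the second excludes it; excising the truth region
#' from the inclusion transcript reproduces the exclusion transcript exactly.
#' `SNV_paralog` builds an equal-length pair differing only at isolated
#' substitutions; `NONE` an identical pair.
#'
#' @param event_type One of `ES`, `AA`, `AD`, `IR`, `AF`, `AL`, `MX`,
#'   `SNV_paralog`, `NONE`.
#' @param as_length Alternative-region length (default 60).
#' @param exon_length Flanking exon length (default 120).
#' @param shared_length Shared block length for AF/AL (default 300).
#' @param alt_lengths Lengths of the two alternative first/last exons for
#'   AF/AL (default `c(60, 40)`).
#' @param n_snv Number of substitutions planted in shared sequence.
#' @param seed Seed; `NULL` uses the current RNG state.
#' @param id_prefix Prefix for the two transcript ids (`_t1`, `_t2`).
#' @param k_floor,k_cap Repeat-freeness window: pairs are resampled until
#'   `select_k_pair() <= k_cap`.
#' @param max_attempts Rejection-sampling cap (default 1000).
#' @return List with `transcripts` (2-row tibble) and `truth` (1-row tibble).
#' @examples
#' fx <- gen_event_pair("IR", seed = 1)
#' substr(fx$transcripts$seq[1], fx$truth$start_a, fx$truth$start_a + 1) # GT
#' @export
gen_event_pair <- function(event_type = EVENT_TYPES, as_length = 60L,
                           exon_length = 120L, shared_length = 300L,
                           alt_lengths = c(60L, 40L), n_snv = 0L,
                           seed = NULL, id_prefix = "fx1",
                           k_floor = 5L, k_cap = 15L, max_attempts = 1000L) {
  event_type <- match.arg(event_type, c(EVENT_TYPES, "SNV_paralog", "NONE"))
  run <- function() {
    for (attempt in seq_len(max_attempts)) {
      fx <- try(build_fixture(event_type, as_length, exon_length,
                              shared_length, alt_lengths, n_snv, id_prefix),
                silent = TRUE)
      if (inherits(fx, "try-error")) next
      k <- try(select_k_pair(fx$transcripts$seq[1], fx$transcripts$seq[2],
                             k_floor), silent = TRUE)
      if (inherits(k, "try-error") || k > k_cap) next
      return(fx)
    }
    rlang::abort("rejection sampling exhausted: fixture parameters too tight")
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

build_fixture <- function(event_type, as_length, exon_length, shared_length,
                          alt_lengths, n_snv, id_prefix) {
  id1 <- paste0(id_prefix, "_t1")
  id2 <- paste0(id_prefix, "_t2")
  snv_pos <- integer()
  if (event_type %in% c("ES", "AA", "AD", "IR")) {
    M <- plant_region(event_type, as_length)
    repeat {
      e1 <- random_dna(exon_length)
      if (substr(e1, exon_length, exon_length) != substr(M, as_length, as_length)) break
    }
    repeat {
      e2 <- random_dna(exon_length)
      if (substr(e2, 1L, 1L) != substr(M, 1L, 1L)) break
    }
    e1_excl <- e1
    if (n_snv > 0L) {
      planted <- plant_substitutions(e1, n_snv, spacing = 34L, margin = 20L)
      e1_excl <- planted$seq
      snv_pos <- planted$pos
    }
    t1 <- paste0(e1, M, e2)
    t2 <- paste0(e1_excl, e2)
    truth <- truth_row(id1, id2, event_type,
                       exon_length + 1L, exon_length + as_length,
                       exon_length + 1L, exon_length, n_snv, snv_pos)
  } else if (event_type %in% c("AF", "AL")) {
    s <- random_dna(shared_length)
    repeat {
      x <- random_dna(alt_lengths[1])
      y <- random_dna(alt_lengths[2])
      if (substr(x, 1L, 1L) != substr(y, 1L, 1L) &&
          substr(x, alt_lengths[1], alt_lengths[1]) !=
            substr(y, alt_lengths[2], alt_lengths[2])) break
    }
    s_t1 <- s
    if (n_snv > 0L) {
      planted <- plant_substitutions(s, n_snv, spacing = 34L, margin = 20L)
      s_t1 <- s # substitutions go on the second transcript's shared block
      s2 <- planted$seq
      snv_pos <- planted$pos
    } else {
      s2 <- s
    }
    if (event_type == "AF") {
      t1 <- paste0(x, s_t1)
      t2 <- paste0(y, s2)
      truth <- truth_row(id1, id2, "AF", 1L, alt_lengths[1], 1L, alt_lengths[2],
                         n_snv, snv_pos)
    } else {
      t1 <- paste0(s_t1, x)
      t2 <- paste0(s2, y)
      truth <- truth_row(id1, id2, "AL",
                         shared_length + 1L, shared_length + alt_lengths[1],
                         shared_length + 1L, shared_length + alt_lengths[2],
                         n_snv, snv_pos)
    }
  } else if (event_type == "MX") {
    e1 <- random_dna(exon_length)
    e2 <- random_dna(exon_length)
    repeat {
      x <- random_dna(as_length)
      y <- random_dna(as_length)
      if (substr(x, 1L, 1L) != substr(y, 1L, 1L) &&
          substr(x, as_length, as_length) != substr(y, as_length, as_length)) break
    }
    e1_b <- e1
    if (n_snv > 0L) {
      planted <- plant_substitutions(e1, n_snv, spacing = 34L, margin = 20L)
      e1_b <- planted$seq
      snv_pos <- planted$pos
    }
    t1 <- paste0(e1, x, e2)
    t2 <- paste0(e1_b, y, e2)
    truth <- truth_row(id1, id2, "MX",
                       exon_length + 1L, exon_length + as_length,
                       exon_length + 1L, exon_length + as_length,
                       n_snv, snv_pos)
  } else if (event_type == "SNV_paralog") {
    bg <- random_dna(3L * exon_length)
    planted <- plant_substitutions(bg, max(n_snv, 1L), spacing = 34L, margin = 20L)
    t1 <- bg
    t2 <- planted$seq
    snv_pos <- planted$pos
    truth <- truth_row(id1, id2, "SNV_paralog", 0L, -1L, 0L, -1L,
                       length(snv_pos), snv_pos)
  } else { # NONE
    bg <- random_dna(3L * exon_length)
    t1 <- bg
    t2 <- bg
    truth <- truth_row(id1, id2, "NONE", 0L, -1L, 0L, -1L, 0L)
  }
  list(
    transcripts = tibble::tibble(id = c(id1, id2), seq = c(t1, t2)),
    truth = truth
  )
}

#' Corrupt a sequence with long-read-style errors
#'
#' Plants 1-2 nt deletions (the dominant third-generation sequencing error
#' mode) and single-nucleotide substitutions at Poisson-sampled counts and
#' uniform positions, keeping every error at least `guard` nt away from
#' protected positions (truth region boundaries) and from other errors so
#' that truth labels stay valid.
#'
#' @param seq DNA string.
#' @param gap_rate Expected deletions per base (in `[0, 0.05]`).
#' @param snv_rate Expected substitutions per base (in `[0, 0.05]`).
#' @param seed Seed; `NULL` uses the current RNG state.
#' @param protect Integer positions (on `seq`) that errors must stay clear of.
#' @param guard Exclusion radius around protected positions and other errors.
#' @return List with `seq` (corrupted) and `errors` (tibble: `type`, `pos`,
#'   `len`, positions on the original sequence).
#' @export
corrupt_tgs <- function(seq, gap_rate = 0.005, snv_rate = 0, seed = NULL,
                        protect = integer(), guard = 20L) {
  stopifnot(gap_rate >= 0, gap_rate <= 0.05, snv_rate >= 0, snv_rate <= 0.05)
  run <- function() {
    n <- nchar(seq)
    n_gap <- stats::rpois(1L, gap_rate * n)
    n_sub <- stats::rpois(1L, snv_rate * n)
    n_err <- n_gap + n_sub
    if (n_err == 0L) {
      return(list(seq = seq,
                  errors = tibble::tibble(type = character(),
                                          pos = integer(), len = integer())))
    }
    ok <- rep(TRUE, n)
    ok[seq_len(min(guard, n))] <- FALSE
    ok[seq.int(max(1L, n - guard), n)] <- FALSE
    for (p in protect) {
      ok[max(1L, p - guard):min(n, p + guard)] <- FALSE
    }
    cand <- sample(which(ok))
    pos <- integer()
    for (p in cand) {
      if (length(pos) == n_err) break
      if (all(abs(pos - p) > 2L * guard)) pos <- c(pos, p)
    }
    types <- rep(c("gap", "snv"), c(n_gap, n_sub))[seq_along(pos)]
    lens <- ifelse(types == "gap", sample(1:2, length(pos), replace = TRUE), 1L)
    errors <- tibble::tibble(type = types, pos = pos, len = as.integer(lens)) |>
      dplyr::arrange(dplyr::desc(.data$pos))
    out <- seq
    for (i in seq_len(nrow(errors))) {
      e <- errors[i, ]
      if (e$type == "gap") {
        out <- paste0(substr(out, 1L, e$pos - 1L),
                      substr(out, e$pos + e$len, nchar(out)))
      } else {
        base <- substr(out, e$pos, e$pos)
        substr(out, e$pos, e$pos) <- sample(setdiff(BASES, base), 1L)
      }
    }
    list(seq = out, errors = dplyr::arrange(errors, .data$pos))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Generate a full ground-truthed dataset
#'
#' Builds `n_per_type` transcript pairs for each requested event type, with
#' exact truth records, optionally corrupted with long-read-style errors.
#' When `dir` is given, writes `transcripts.fasta` and `truth.tsv` there.
#'
#' @param n_per_type Pairs per event type.
#' @param seed Seed.
#' @param types Event types to generate (default all seven).
#' @param n_snv Substitutions planted per pair (default 0).
#' @param seqtype_noise `"none"` or `"tgs"` (1-2 nt gap corruption).
#' @param gap_rate Gap rate when `seqtype_noise = "tgs"`.
#' @param dir Optional output directory.
#' @param ... Passed to [gen_event_pair()].
#' @return List with `transcripts` and `truth` tibbles.
#' @export
gen_dataset <- function(n_per_type = 20L, seed = 7L, types = EVENT_TYPES,
                        n_snv = 0L, seqtype_noise = c("none", "tgs"),
                        gap_rate = 0.005, dir = NULL, ...) {
  seqtype_noise <- match.arg(seqtype_noise)
  res <- withr::with_seed(seed, {
    fixtures <- purrr::map(types, function(type) {
      purrr::map(seq_len(n_per_type), function(i) {
        gen_event_pair(type, n_snv = n_snv, seed = NULL,
                       id_prefix = sprintf("%s%03d", tolower(type), i), ...)
      })
    }) |> purrr::flatten()
    transcripts <- purrr::map_dfr(fixtures, "transcripts")
    truth <- purrr::map_dfr(fixtures, "truth")
    if (seqtype_noise == "tgs") {
      # deletions upstream of (or inside) a region shift its coordinates;
      # truth is updated so that it stays exact on the corrupted sequences
      shift_coord <- function(coord, errors) {
        gaps <- errors[errors$type == "gap", ]
        as.integer(coord - sum(gaps$len[gaps$pos < coord]))
      }
      for (r in seq_len(nrow(truth))) {
        tr <- truth[r, ]
        for (col in c("id_a", "id_b")) {
          i <- match(tr[[col]], transcripts$id)
          if (col == "id_a") {
            prot <- c(tr$start_a, tr$end_a)
          } else {
            prot <- c(tr$start_b, tr$end_b)
          }
          cor <- corrupt_tgs(transcripts$seq[i], gap_rate = gap_rate,
                             protect = prot[prot > 0])
          transcripts$seq[i] <- cor$seq
          if (col == "id_a" && truth$end_a[r] >= truth$start_a[r]) {
            truth$start_a[r] <- shift_coord(truth$start_a[r], cor$errors)
            truth$end_a[r] <- shift_coord(truth$end_a[r], cor$errors)
          } else if (col == "id_b") {
            empty_b <- truth$end_b[r] < truth$start_b[r]
            truth$start_b[r] <- shift_coord(truth$start_b[r], cor$errors)
            truth$end_b[r] <- if (empty_b) truth$start_b[r] - 1L else
              shift_coord(truth$end_b[r], cor$errors)
          }
        }
      }
    }
    list(transcripts = transcripts, truth = truth)
  })
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_fasta(res$transcripts, file.path(dir, "transcripts.fasta"))
    readr::write_tsv(res$truth, file.path(dir, "truth.tsv"))
  }
  res
}

#' Generate a labeled dataset for classifier training
#'
#' Builds ES/AA/AD/IR event pairs whose alternative-region boundary
#' dinucleotides follow the intron-fragment logic of each class, so the
#' classes are discriminable from sequence features, and returns the events
#' in the same shape the identification module emits.
#'
#' @param n_per_class Events per class.
#' @param seed Seed.
#' @return List with `transcripts`, `events` (UNTYPED events tibble) and
#'   `labels` (character vector parallel to events).
#' @export
gen_labeled_dataset <- function(n_per_class = 200L, seed = 7L) {
  withr::with_seed(seed, {
    classes <- c("ES", "AA", "AD", "IR")
    fixtures <- purrr::map(classes, function(type) {
      purrr::map(seq_len(n_per_class), function(i) {
        gen_event_pair(
          type,
          as_length = sample(seq(30L, 120L, 3L), 1L),
          exon_length = sample(100:160, 1L),
          seed = NULL,
          id_prefix = sprintf("%s%04d", tolower(type), i)
        )
      })
    }) |> purrr::flatten()
    transcripts <- purrr::map_dfr(fixtures, "transcripts")
    truth <- purrr::map_dfr(fixtures, "truth")
    events <- truth |>
      dplyr::transmute(
        event_id = make_event_id(.data$id_a, .data$id_b, .data$start_a, .data$end_a),
        id_a = .data$id_a, id_b = .data$id_b,
        event_type = "UNTYPED",
        start_a = .data$start_a, end_a = .data$end_a,
        start_b = .data$start_b, end_b = .data$end_b,
        n_snv = 0L, source = NA_character_,
        prob_ES = NA_real_, prob_AA = NA_real_,
        prob_AD = NA_real_, prob_IR = NA_real_
      )
    list(transcripts = transcripts, events = events,
         labels = truth$event_type)
  })
}

#' Simulate abundances for differential-splicing analysis
#'
#' Creates `n_events` two-isoform events across two conditions with
#' `n_reps` replicates each: `n_true` events have a planted PSI difference of
#' `delta` between conditions, the rest share a common PSI. Per-transcript
#' abundances carry multiplicative lognormal noise.
#'
#' @param n_events Total events.
#' @param n_true Events with a true PSI difference.
#' @param delta Planted PSI difference (condition B minus A).
#' @param n_reps Replicates per condition.
#' @param noise_sd Lognormal sigma of the abundance noise (0.2 means roughly
#'   20 percent multiplicative noise).
#' @param base_psi PSI in condition A for true events (default 0.3).
#' @param seed Seed.
#' @return List with `events`, `abundances` (condition/replicate rows) and
#'   `truth` (`event_id`, `is_true`, `psi_a`, `psi_b`).
#' @export
gen_psi_dataset <- function(n_events = 200L, n_true = 20L, delta = 0.4,
                            n_reps = 5L, noise_sd = 0.2, base_psi = 0.3,
                            seed = 1L) {
  stopifnot(n_true <= n_events, base_psi + delta <= 1)
  withr::with_seed(seed, {
    ids <- sprintf("ev%04d", seq_len(n_events))
    is_true <- seq_len(n_events) <= n_true
    psi_a <- ifelse(is_true, base_psi, stats::runif(n_events, 0.2, 0.8))
    psi_b <- ifelse(is_true, base_psi + delta, psi_a)
    events <- tibble::tibble(
      event_id = make_event_id(paste0(ids, "_t1"), paste0(ids, "_t2"), 1L, 50L),
      id_a = paste0(ids, "_t1"), id_b = paste0(ids, "_t2"),
      event_type = "UNTYPED",
      start_a = 1L, end_a = 50L, start_b = 1L, end_b = 0L,
      n_snv = 0L, source = NA_character_,
      prob_ES = NA_real_, prob_AA = NA_real_,
      prob_AD = NA_real_, prob_IR = NA_real_
    )
    grid <- tidyr::crossing(
      i = seq_len(n_events),
      condition = c("A", "B"),
      replicate = as.character(seq_len(n_reps))
    )
    abundances <- grid |>
      dplyr::mutate(
        psi = ifelse(.data$condition == "A", psi_a[.data$i], psi_b[.data$i]),
        total = stats::rlnorm(dplyr::n(), log(100), 0.3),
        incl = .data$total * .data$psi *
          exp(stats::rnorm(dplyr::n(), 0, noise_sd)),
        excl = .data$total * (1 - .data$psi) *
          exp(stats::rnorm(dplyr::n(), 0, noise_sd))
      )
    long <- dplyr::bind_rows(
      abundances |>
        dplyr::transmute(transcript_id = paste0(ids[.data$i], "_t1"),
                         .data$condition, .data$replicate,
                         abundance = .data$incl),
      abundances |>
        dplyr::transmute(transcript_id = paste0(ids[.data$i], "_t2"),
                         .data$condition, .data$replicate,
                         abundance = .data$excl)
    )
    list(
      events = events,
      abundances = long,
      truth = tibble::tibble(event_id = events$event_id,
                             is_true = is_true, psi_a = psi_a, psi_b = psi_b)
    )
  })
}

#' Generate a background for an exhaustive substitution scan
#'
#' Returns a random background together with one single-substitution mutant
#' per internal position. The background is rejection-sampled so that for
#' every mutant the k-mers shared with the background are exactly the
#' background k-mers clear of the substituted position: accidental
#' cross-matches (a mutated k-mer recreating a background k-mer elsewhere)
#' would otherwise make the bubble expectation ill-defined at isolated
#' positions.
#'
#' @param length Background length (default 60).
#' @param seed Seed; `NULL` uses the current RNG state.
#' @param k_floor Floor passed to [select_k_pair()].
#' @param max_attempts Rejection cap.
#' @return List with `bg` and `mutants` (tibble: `pos`, `seq`, `k`).
#' @export
gen_substitution_scan <- function(length = 60L, seed = NULL, k_floor = 5L,
                                  max_attempts = 200L) {
  run <- function() {
    for (attempt in seq_len(max_attempts)) {
      bg <- random_dna(length)
      chars <- strsplit(bg, "")[[1]]
      mutants <- purrr::map_dfr(2:(length - 1L), function(p) {
        ch <- chars
        ch[p] <- setdiff(BASES, ch[p])[sample.int(3L, 1L)]
        tibble::tibble(pos = p, seq = paste(ch, collapse = ""))
      })
      ks <- purrr::map_int(seq_len(nrow(mutants)), function(i) {
        k <- try(select_k_pair(bg, mutants$seq[i], k_floor), silent = TRUE)
        if (inherits(k, "try-error")) return(NA_integer_)
        p <- mutants$pos[i]
        bg_km <- seq_kmers(bg, k)
        starts <- seq_along(bg_km)
        expected <- bg_km[starts < p - k + 1L | starts > p]
        shared <- intersect(seq_kmers(mutants$seq[i], k), bg_km)
        if (setequal(shared, expected)) as.integer(k) else NA_integer_
      })
      if (!anyNA(ks)) {
        mutants$k <- ks
        return(list(bg = bg, mutants = mutants))
      }
    }
    rlang::abort("rejection sampling exhausted for substitution scan background")
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Generate a pair differing by one clean insertion
#'
#' Plants an insertion of `ins_length` nt at the middle of a random
#' background, rejection-sampled so that the pair is repeat-free at a small k
#' and the insert's boundary bases differ from the adjacent background bases
#' (otherwise the junction is ambiguous and the arm-count expectation is not
#' well defined).
#'
#' @param ins_length Insertion length.
#' @param length Background length (default 60).
#' @param seed Seed; `NULL` uses the current RNG state.
#' @param k_floor,k_cap Repeat-freeness bounds.
#' @param max_attempts Rejection cap.
#' @return List with `transcripts` (insertion carrier first), `pos` (1-based
#'   first inserted position on the carrier) and `ins_length`.
#' @export
gen_insertion_pair <- function(ins_length = 3L, length = 60L, seed = NULL,
                               k_floor = 5L, k_cap = 15L,
                               max_attempts = 1000L) {
  run <- function() {
    for (attempt in seq_len(max_attempts)) {
      bg <- random_dna(length)
      ins <- random_dna(ins_length)
      p <- length %/% 2L
      if (substr(ins, 1L, 1L) == substr(bg, p + 1L, p + 1L)) next
      if (substr(ins, ins_length, ins_length) == substr(bg, p, p)) next
      carrier <- paste0(substr(bg, 1L, p), ins, substr(bg, p + 1L, length))
      k <- try(select_k_pair(bg, carrier, k_floor), silent = TRUE)
      if (inherits(k, "try-error") || k > k_cap) next
      # the shared k-mers must be exactly the background k-mers clear of the
      # junction; accidental cross-matches would plant spurious anchors
      bg_km <- seq_kmers(bg, k)
      starts <- seq_along(bg_km)
      expected <- bg_km[starts <= p - k + 1L | starts >= p + 1L]
      if (!setequal(intersect(seq_kmers(carrier, k), bg_km), expected)) next
      return(list(
        transcripts = tibble::tibble(id = c("ins_t1", "ins_t2"),
                                     seq = c(carrier, bg)),
        pos = p + 1L, ins_length = as.integer(ins_length)
      ))
    }
    rlang::abort("rejection sampling exhausted for insertion pair")
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Generate a pair with two close substitutions
#'
#' Builds a background and a copy carrying two substitutions separated by
#' `gap` matching bases. At detection k larger than the gap the two variants
#' merge into a single unresolved bubble; a sub-graph at k' no larger than
#' the gap separates them into two SNV bubbles. Backgrounds are
#' rejection-sampled so that the pair is repeat-free at `k` and the local
#' windows around the substitutions are repeat-free at a k' no larger than
#' the gap, making the refinement outcome determined by construction.
#'
#' @param gap Matching bases between the two substitutions (at least 3).
#' @param k Detection k to be used (pass `k_floor = k` to the caller).
#' @param length Background length (default 60).
#' @param seed Seed; `NULL` uses the current RNG state.
#' @param max_attempts Rejection cap.
#' @return List with `transcripts` (2-row tibble), `pos` (the two substituted
#'   positions) and `k`.
#' @export
gen_close_snv_pair <- function(gap = 4L, k = 8L, length = 60L, seed = NULL,
                               max_attempts = 2000L) {
  stopifnot(gap >= 3L, k > gap)
  run <- function() {
    for (attempt in seq_len(max_attempts)) {
      bg <- random_dna(length)
      p1 <- (length - gap) %/% 2L
      p2 <- p1 + gap + 1L
      chars <- strsplit(bg, "")[[1]]
      chars[p1] <- sample(setdiff(BASES, chars[p1]), 1L)
      chars[p2] <- sample(setdiff(BASES, chars[p2]), 1L)
      mut <- paste(chars, collapse = "")
      if (!kmers_unique_at(bg, k) || !kmers_unique_at(mut, k)) next
      w_lo <- max(1L, p1 - k)
      w_hi <- min(length, p2 + k)
      w1 <- substr(bg, w_lo, w_hi)
      w2 <- substr(mut, w_lo, w_hi)
      if (select_k(w1, 3L) > gap || select_k(w2, 3L) > gap) next
      # shared k'-mers of the two arm windows must align positionally,
      # otherwise accidental cross-matches fragment the sub-graph
      kp <- select_k_pair(w1, w2, 3L)
      s1 <- seq_kmers(w1, kp)
      s2 <- seq_kmers(w2, kp)
      if (!setequal(intersect(s1, s2), s1[s1 == s2])) next
      return(list(
        transcripts = tibble::tibble(id = c("ref_t1", "ref_t2"),
                                     seq = c(bg, mut)),
        pos = c(p1, p2), k = k
      ))
    }
    rlang::abort("rejection sampling exhausted for close-substitution pair")
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
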