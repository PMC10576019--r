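#' Run configuration for identification and event calling
#'
#' Collects the tunable parameters of the graph-based identification pipeline.
#' The single switch most users need is `seqtype`: `"assembly"` for
#' error-corrected assembled transcripts and `"isoseq"` for long-read
#' full-length transcripts, which carry characteristic 1-2 nt indel errors.
#' Switching to `"isoseq"` raises the tolerated number of SNV-induced bubbles
#' per pair from 2 to 5 and activates a filter that drops bubbles shaped like
#' 1-2 nt gaps (longer arm shorter than k + 2 nodes) before event calling.
#'
#' @param seqtype `"assembly"` or `"isoseq"`.
#' @param snv_tolerance Maximum number of SNV-induced bubbles a transcript pair
#'   may contain and still be called alternatively spliced; pairs above the
#'   tolerance are treated as putative paralogs. Defaults to 2 for assemblies
#'   and 5 for Iso-Seq reads.
#' @param afalmx_arm_fraction AF/AL/MX positional rule: the bubble arm on the
#'   shorter transcript must span less than this fraction of that transcript's
#'   length. Default 0.30.
#' @param evalue_cutoff E-value cutoff applied when importing BLAST tabular
#'   hits as candidate pairs. Default 1e-10.
#' @param k_floor Smallest k considered when selecting the graph k for a pair.
#'   Default 5.
#' @param refine_k_floor Smallest k' considered when rebuilding an unresolved
#'   bubble's arms as a sub-graph. Kept lower (default 3) than `k_floor`
#'   because arm sequences are short and local, and close substitutions can
#'   only be split when k' does not exceed the gap between them.
#' @param screen_k,min_shared Parameters of the internal all-versus-all pairing
#'   screen: transcript pairs sharing at least `min_shared` distinct
#'   `screen_k`-mers become candidate pairs.
#' @param recursive_refine Recursively refine bubbles that remain unresolved
#'   inside a sub-graph. Off by default (one level of refinement).
#' @param max_refine_depth Depth cap for recursive refinement.
#' @param motif_path Optional path to a motif list (one motif per line) used by
#'   the feature module; `NULL` means the shipped default list.
#' @param random_seed Seed recorded with the run.
#'
#' @return An object of class `as_config` (a named list).
#' @examples
#' as_config("isoseq")$snv_tolerance
#' @export
as_config <- function(seqtype = c("assembly", "isoseq"),
                      snv_tolerance = NULL,
                      afalmx_arm_fraction = 0.30,
                      evalue_cutoff = 1e-10,
                      k_floor = 5L,
                      refine_k_floor = 3L,
                      screen_k = 15L,
                      min_shared = 20L,
                      recursive_refine = FALSE,
                      max_refine_depth = 5L,
                      motif_path = NULL,
                      random_seed = 1L) {
  seqtype <- match.arg(seqtype)
  if (is.null(snv_tolerance)) {
    snv_tolerance <- if (seqtype == "isoseq") 5L else 2L
  }
  stopifnot(
    snv_tolerance >= 0,
    afalmx_arm_fraction > 0, afalmx_arm_fraction < 1,
    k_floor >= 3, refine_k_floor >= 3,
    screen_k >= 8, min_shared >= 1,
    max_refine_depth >= 1
  )
  structure(
    list(
      seqtype = seqtype,
      snv_tolerance = as.integer(snv_tolerance),
      afalmx_arm_fraction = afalmx_arm_fraction,
      evalue_cutoff = evalue_cutoff,
      k_floor = as.integer(k_floor),
      refine_k_floor = as.integer(refine_k_floor),
      screen_k = as.integer(screen_k),
      min_shared = as.integer(min_shared),
      recursive_refine = isTRUE(recursive_refine),
      max_refine_depth = as.integer(max_refine_depth),
      motif_path = motif_path,
      random_seed = as.integer(random_seed)
    ),
    class = "as_config"
  )
}

#' @export
print.as_config <- function(x, ...) {
  cat("<as_config>\n")
  cat("  seqtype:            ", x$seqtype, "\n")
  cat("  snv_tolerance:      ", x$snv_tolerance, "\n")
  cat("  afalmx_arm_fraction:", x$afalmx_arm_fraction, "\n")
  cat("  k_floor / refine:   ", x$k_floor, "/", x$refine_k_floor, "\n")
  cat("  pairing screen:     ", x$min_shared, "shared", x$screen_k, "-mers\n")
  invisible(x)
}
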