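# The core contribution: banded 2D prefix beam search maximizing the product
# of the two reads' sequence probabilities, and the full 1D2 pipeline.

new_pair_decode_result <- function(sequence, lp1, lp2, read_id = "pair",
                                   extra = list()) {
  structure(c(list(read_id = read_id, sequence = sequence,
                   log_prob_combined = lp1 + lp2,
                   log_prob_1 = lp1, log_prob_2 = lp2), extra),
            class = "pair_decode_result")
}

#' @export
print.pair_decode_result <- function(x, ...) {
  cat(sprintf(paste0("<pair_decode_result> %s: %d bases, combined log_prob ",
                     "%.4f (read1 %.4f + read2 %.4f)\n"),
              x$read_id, nchar(x$sequence), x$log_prob_combined,
              x$log_prob_1, x$log_prob_2))
  invisible(x)
}

#' Banded 2D pair beam search
#'
#' Finds the consensus sequence maximizing
#' `P(sequence | read1) * P(sequence | read2)` — the product of the two CTC
#' forward probabilities, i.e. the maximum a posteriori consensus under a
#' flat sequence prior and independent reads. Beams are sequence prefixes
#' carrying CTC prefix-forward masses for both reads; frames of read 1 are
#' swept in order while each prefix's read-2 masses are maintained over the
#' envelope's admissible frame range, so the search explores only the region
#' of the `(t1, t2)` plane the envelope admits. With a [full_envelope()] and
#' a beam wide enough to hold every prefix the search is exact.
#'
#' @param p1,p2 [probability_profile()] objects (already co-oriented; see
#'   [reverse_complement_profile()]).
#' @param env an `alignment_envelope` with dimensions `(T1, T2)` matching the
#'   profiles.
#' @param beam_width number of prefixes kept per frame (default 25).
#' @return An object of class `pair_decode_result` with the consensus
#'   `sequence`, `log_prob_combined` and the per-read components
#'   `log_prob_1`, `log_prob_2`.
#' @export
pair_beam_search <- function(p1, p2, env, beam_width = 25L) {
  stopifnot(inherits(p1, "probability_profile"),
            inherits(p2, "probability_profile"))
  validate_envelope(env)
  if (env$T1 != p1$T || env$T2 != p2$T)
    stop(sprintf("envelope is %d x %d but profiles have %d and %d frames",
                 env$T1, env$T2, p1$T, p2$T))
  beam_width <- as.integer(beam_width)
  if (is.na(beam_width) || beam_width < 1L)
    stop("`beam_width` must be a positive integer")
  r <- ctc_beam_2d_cpp(log_probs(p1), log_probs(p2), env$lo, env$hi, beam_width)
  new_pair_decode_result(r$sequence, r$log_prob_1, r$log_prob_2,
                         read_id = paste0(p1$read_id, "+", p2$read_id))
}

#' Full 1D2 pair decoding pipeline
#'
#' Runs the complete consensus procedure on a pair of profiles derived from
#' the same molecule: (optionally) reverse-complement the second profile onto
#' the first read's strand; Viterbi-decode each profile; globally align the
#' two basecalls with a banded Needleman-Wunsch to obtain a guide alignment;
#' map each basecall to signal-frame intervals; lift the guide alignment into
#' an alignment envelope with padding; and run the banded 2D beam search
#' inside it.
#'
#' A guide alignment whose identity falls below `min_guide_identity` suggests
#' the reads are not a true pair; the pipeline then either falls back to the
#' full (unbanded) envelope (`low_identity_action = "fallback"`, sensible for
#' short reads) or refuses (`"error"`).
#'
#' @inheritParams pair_beam_search
#' @param params [align_params()] for the guide alignment.
#' @param padding envelope padding in frames (default 150).
#' @param complement_strand_2 is `p2` a complement-strand read? If `TRUE` it
#'   is reverse-complemented before anything else.
#' @param min_guide_identity guide-alignment identity below which the guide
#'   is considered unreliable (default 0.3).
#' @param low_identity_action `"fallback"` (full envelope) or `"error"`.
#' @return A `pair_decode_result`; the intermediate `guide`, `envelope` and
#'   per-read Viterbi `decodes` are attached as fields.
#' @export
pair_decode_pipeline <- function(p1, p2, params = align_params(),
                                 padding = 150L, beam_width = 25L,
                                 complement_strand_2 = FALSE,
                                 min_guide_identity = 0.3,
                                 low_identity_action = c("fallback", "error")) {
  stopifnot(inherits(p1, "probability_profile"),
            inherits(p2, "probability_profile"))
  low_identity_action <- match.arg(low_identity_action)
  if (complement_strand_2) p2 <- reverse_complement_profile(p2)
  d1 <- viterbi_decode(p1)
  d2 <- viterbi_decode(p2)
  guide <- banded_global_align(d1$sequence, d2$sequence, params)
  guide_identity <- if (guide$alignment_length > 0)
    guide$matches / guide$alignment_length else 0
  if (guide_identity < min_guide_identity &&
      nchar(d1$sequence) > 0 && nchar(d2$sequence) > 0) {
    if (low_identity_action == "error")
      stop(sprintf(paste0("guide alignment identity %.2f is below %.2f; ",
                          "these profiles do not look like a read pair"),
                   guide_identity, min_guide_identity))
    warning(sprintf(paste0("guide alignment identity %.2f is below %.2f; ",
                           "falling back to the full envelope"),
                    guide_identity, min_guide_identity))
    env <- full_envelope(p1$T, p2$T)
  } else if (nchar(d1$sequence) == 0 || nchar(d2$sequence) == 0) {
    # a read whose basecall is empty carries no positional information
    env <- full_envelope(p1$T, p2$T)
  } else {
    env <- build_envelope(path_to_signal_map(d1$path),
                          path_to_signal_map(d2$path),
                          guide, padding = padding)
  }
  res <- pair_beam_search(p1, p2, env, beam_width = beam_width)
  res$guide <- guide
  res$envelope <- env
  res$decodes <- list(d1, d2)
  res
}
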