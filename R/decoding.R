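# Single-read CTC machinery: collapse, forward probability, Viterbi,
# prefix beam search, and an exhaustive enumerator used as a test oracle.

new_decode_result <- function(sequence, log_prob, path = NULL, read_id = "read") {
  structure(list(read_id = read_id, sequence = sequence,
                 log_prob = log_prob, path = path),
            class = "decode_result")
}

#' @export
print.decode_result <- function(x, ...) {
  cat(sprintf("<decode_result> %s: %d bases, log_prob = %.4f\n",
              x$read_id, nchar(x$sequence), x$log_prob))
  if (nchar(x$sequence) > 0)
    cat(strtrim(x$sequence, 60),
        if (nchar(x$sequence) > 60) "...\n" else "\n", sep = "")
  invisible(x)
}

#' Collapse a frame-level label path to a DNA sequence
#'
#' Standard CTC collapse: merge runs of consecutive identical non-blank
#' labels, then delete blanks. Two copies of the same base therefore require
#' an intervening blank to survive as a repeat. Setting
#' `merge_repeats = FALSE` switches to the drop-blanks-only variant in which
#' every non-blank frame emits a base.
#'
#' @param path character vector of per-frame labels over
#'   `c("A","C","G","T","-")` (`"-"` is the blank).
#' @param merge_repeats merge consecutive identical non-blank labels first
#'   (the CTC convention; default `TRUE`).
#' @return A single string over A,C,G,T.
#' @examples
#' collapse_path(c("A", "-", "A"))        # "AA"
#' collapse_path(c("A", "A", "C", "C", "-", "C"))  # "ACC"
#' @export
collapse_path <- function(path, merge_repeats = TRUE) {
  if (length(path) == 0L) return("")
  if (!all(path %in% PROFILE_ALPHABET))
    stop("path labels must be in A, C, G, T, -")
  if (merge_repeats) path <- rle(path)$values
  paste(path[path != "-"], collapse = "")
}

seq_to_codes <- function(sequence) {
  # 0-based base codes for the C++ layer
  if (nchar(sequence) == 0L) return(integer(0))
  match(strsplit(sequence, "")[[1L]], c("A", "C", "G", "T")) - 1L
}

#' CTC forward log-probability of a sequence
#'
#' Computes `log P(sequence | profile)`: the log of the summed probability of
#' every frame-level label path that collapses to `sequence`, via the
#' standard CTC forward recursion over the blank-interleaved expanded label
#' string, in log space with log-sum-exp.
#'
#' @param profile a [probability_profile()].
#' @param sequence a string over A,C,G,T (may be empty).
#' @return Log probability (natural log); `-Inf` when no path of length `T`
#'   can produce `sequence`.
#' @examples
#' p <- probability_profile(matrix(c(0.6, 0.1, 0.1, 0.1, 0.1), 1, 5))
#' exp(forward_probability(p, "A"))  # 0.6
#' exp(forward_probability(p, ""))   # 0.1
#' @export
forward_probability <- function(profile, sequence) {
  stopifnot(inherits(profile, "probability_profile"))
  check_dna(sequence)
  ctc_forward_cpp(log_probs(profile), seq_to_codes(sequence))
}

#' Viterbi (best single path) decoding
#'
#' Finds the label path maximizing the product of per-frame probabilities and
#' collapses it. With per-frame posteriors and no transition model this is the
#' per-frame argmax; ties are broken in alphabet order (A < C < G < T < blank).
#' This is the fast preliminary decoder used to build guide alignments.
#'
#' @param profile a [probability_profile()].
#' @return A `decode_result` with fields `sequence`, `log_prob` (the best
#'   path's log product) and `path`.
#' @export
viterbi_decode <- function(profile) {
  stopifnot(inherits(profile, "probability_profile"))
  m <- profile$probabilities
  best <- max.col(m, ties.method = "first")  # first = alphabet order
  path <- PROFILE_ALPHABET[best]
  lp <- sum(log(m[cbind(seq_len(nrow(m)), best)]))
  new_decode_result(collapse_path(path), lp, path = path,
                    read_id = profile$read_id)
}

#' CTC prefix beam search decoding
#'
#' Heuristic search for the modal sequence of `P(sequence | profile)`. Beams
#' are sequence prefixes, each carrying separate blank-ending and
#' non-blank-ending forward masses updated frame by frame; the `beam_width`
#' prefixes with the largest total mass are kept per frame. As `beam_width`
#' grows the search converges to the exhaustive argmax.
#'
#' @param profile a [probability_profile()].
#' @param beam_width number of prefixes kept per frame (default 25).
#' @return A `decode_result`; `log_prob` is the returned sequence's forward
#'   log mass under the (possibly pruned) prefix recursion.
#' @export
beam_search_decode <- function(profile, beam_width = 25L) {
  stopifnot(inherits(profile, "probability_profile"))
  beam_width <- as.integer(beam_width)
  if (is.na(beam_width) || beam_width < 1L)
    stop("`beam_width` must be a positive integer")
  r <- ctc_beam_1d_cpp(log_probs(profile), beam_width)
  new_decode_result(r$sequence, r$log_prob, read_id = profile$read_id)
}

all_sequences_upto <- function(max_len) {
  # every DNA string of length 0..max_len, shortest first then lexicographic
  out <- ""
  for (L in seq_len(max_len)) {
    g <- do.call(expand.grid,
                 rev(rep(list(c("A", "C", "G", "T")), L)))[, L:1, drop = FALSE]
    out <- c(out, do.call(paste0, g))
  }
  out
}

#' Exhaustive decoding by enumeration
#'
#' The intractable exact search, implemented for testing at tiny frame
#' counts: evaluates [forward_probability()] for every sequence of length up
#' to `min(max_len, T)` and returns the argmax. Refuses profiles with more
#' than 8 frames.
#'
#' @param profile a [probability_profile()] with `T <= 8`.
#' @param max_len maximum sequence length to consider (default `T`).
#' @return A `decode_result`; ties broken shortest-first, then
#'   lexicographically.
#' @export
enumerate_decode <- function(profile, max_len = profile$T) {
  stopifnot(inherits(profile, "probability_profile"))
  if (profile$T > 8L)
    stop("enumerate_decode is an exhaustive test oracle and refuses T > 8 ",
         "(got T = ", profile$T, ")")
  cands <- all_sequences_upto(min(max_len, profile$T))
  lp <- vapply(cands, function(s) forward_probability(profile, s), numeric(1))
  best <- which.max(lp)  # cands are ordered shortest-first, lexicographic
  new_decode_result(cands[best], unname(lp[best]), read_id = profile$read_id)
}
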