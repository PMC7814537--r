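# Accuracy evaluation: identity = matches / alignment length, the standard
# read-accuracy metric, computed against a known truth by global alignment.

#' Alignment identity of a call against a reference
#'
#' Globally aligns `query` to `ref` (banded Needleman-Wunsch; the band is
#' widened automatically until it is feasible, so the result is a true global
#' alignment) and reports identity = (number of match columns) / (total
#' alignment columns, i.e. matches + mismatches + gaps). Every column counts,
#' including end gaps — the strict convention.
#'
#' @param ref,query non-empty DNA strings.
#' @param params an [align_params()]; `band_half_width` is a starting value.
#' @return A one-row [tibble::tibble()] of class `accuracy_report` with
#'   columns `matches`, `mismatches`, `gaps`, `alignment_length`, `identity`.
#' @examples
#' compute_identity("ACGT", "ACGA")$identity  # 0.75
#' @export
compute_identity <- function(ref, query, params = align_params()) {
  check_dna(ref, allow_empty = FALSE)
  check_dna(query, allow_empty = FALSE)
  # a band narrower than the length difference cannot hold the global
  # optimum; start from a width that can, then widen on infeasibility
  w <- max(params$band_half_width,
           abs(nchar(ref) - nchar(query)) + 32L)
  repeat {
    params$band_half_width <- w
    g <- tryCatch(banded_global_align(ref, query, params),
                  error = function(e) NULL)
    if (!is.null(g)) break
    w <- w * 2L
    if (w > 4L * max(nchar(ref), nchar(query)))
      stop("could not find a feasible band")  # unreachable in practice
  }
  both <- !is.na(g$columns$i) & !is.na(g$columns$j)
  matches <- sum(both & g$columns$a == g$columns$b)
  out <- tibble::tibble(matches = matches,
                        mismatches = sum(both) - matches,
                        gaps = g$alignment_length - sum(both),
                        alignment_length = g$alignment_length,
                        identity = matches / g$alignment_length)
  class(out) <- c("accuracy_report", class(out))
  out
}

#' Summarize a batch of accuracy reports
#'
#' The headline summary of a basecalling benchmark is the median identity;
#' quartiles give the spread.
#'
#' @param reports a list of [compute_identity()] reports, a single stacked
#'   report data frame, or a bare numeric vector of identities.
#' @return A one-row tibble with `n`, `median_identity`, `q1`, `q3`.
#' @export
summarize_batch <- function(reports) {
  ids <- if (is.numeric(reports)) reports
         else if (is.data.frame(reports)) reports$identity
         else vapply(reports, function(r) r$identity, numeric(1))
  if (length(ids) < 1L) stop("need at least one report")
  q <- stats::quantile(ids, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  tibble::tibble(n = length(ids), median_identity = q[2L],
                 q1 = q[1L], q3 = q[3L])
}

#' Identities from a PAF alignment file
#'
#' For users evaluating against a reference with an external aligner:
#' reads identity directly from the standard 12-column PAF text format as
#' (residue matches, column 10) / (alignment block length, column 11).
#'
#' @param path PAF file.
#' @return A tibble with `query`, `target`, `matches`, `alignment_length`,
#'   `identity` per record.
#' @export
read_paf_identity <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  f <- strsplit(lines, "\t")
  if (any(lengths(f) < 12L)) stop("malformed PAF: fewer than 12 columns")
  tibble::tibble(query = vapply(f, `[`, "", 1L),
                 target = vapply(f, `[`, "", 6L),
                 matches = as.numeric(vapply(f, `[`, "", 10L)),
                 alignment_length = as.numeric(vapply(f, `[`, "", 11L)),
                 identity = as.numeric(vapply(f, `[`, "", 10L)) /
                            as.numeric(vapply(f, `[`, "", 11L)))
}
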