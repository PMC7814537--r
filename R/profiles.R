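#' @useDynLib pairconsensus, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# canonical column order of every profile matrix
PROFILE_ALPHABET <- c("A", "C", "G", "T", "-")

#' Construct a probability profile
#'
#' A probability profile is the output of a CTC-trained basecaller network:
#' for each of `T` signal frames, a softmax distribution over the four DNA
#' bases plus a blank gap symbol. It is the substrate every decoder in this
#' package consumes; the package starts at the profile, not at raw current.
#'
#' @param probabilities numeric matrix with `T >= 1` rows and 5 columns giving
#'   `P(label | frame)` over the ordered alphabet A, C, G, T, blank.
#' @param read_id text label for the read.
#' @param column_order character vector of length 5 declaring the column
#'   order of `probabilities` (a permutation of `c("A","C","G","T","-")`);
#'   columns are reordered to the canonical order.
#' @return An object of class `probability_profile` with elements `read_id`,
#'   `probabilities` (T x 5, canonical column order) and `T`.
#' @examples
#' p <- probability_profile(matrix(c(1, 0, 0, 0, 0), 1, 5))
#' p$T
#' @export
probability_profile <- function(probabilities, read_id = "read",
                                column_order = PROFILE_ALPHABET) {
  probabilities <- as.matrix(probabilities)
  if (!is.numeric(probabilities) || ncol(probabilities) != 5L)
    stop("`probabilities` must be a numeric matrix with 5 columns")
  if (nrow(probabilities) < 1L)
    stop("a profile needs at least one frame (T >= 1)")
  if (!setequal(column_order, PROFILE_ALPHABET) || length(column_order) != 5L)
    stop("`column_order` must be a permutation of A, C, G, T, -")
  probabilities <- probabilities[, match(PROFILE_ALPHABET, column_order),
                                 drop = FALSE]
  dimnames(probabilities) <- list(NULL, PROFILE_ALPHABET)
  bad <- which(probabilities < 0, arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("negative probability at row %d", bad[1L, 1L]))
  if (any(probabilities > 1))
    stop("probabilities must lie in [0, 1]")
  rs <- rowSums(probabilities)
  off <- which(abs(rs - 1) > 1e-6)
  if (length(off) > 0L)
    stop(sprintf("row %d sums to %.8f, not 1 (tolerance 1e-6)", off[1L], rs[off[1L]]))
  # renormalize drift within tolerance; rows already summing to 1 at double
  # precision are left untouched so binary round-trips stay bit-exact
  drift <- abs(rs - 1) > 1e-12
  if (any(drift))
    probabilities[drift, ] <- probabilities[drift, , drop = FALSE] / rs[drift]
  structure(list(read_id = as.character(read_id),
                 probabilities = probabilities,
                 T = nrow(probabilities)),
            class = "probability_profile")
}

#' @export
print.probability_profile <- function(x, ...) {
  cat(sprintf("<probability_profile> %s: %d frames x 5 labels (A,C,G,T,-)\n",
              x$read_id, x$T))
  invisible(x)
}

log_probs <- function(profile) {
  # natural-log profile; exact zeros become -Inf sentinels
  lp <- suppressWarnings(log(profile$probabilities))
  lp[profile$probabilities == 0] <- -Inf
  lp
}

#' Read a probability profile from disk
#'
#' Two formats are supported. `"csv"` is a plain-text table: a header line
#' `# alphabet=ACGT-` (any permutation; declares the column order), then one
#' comma-separated row of 5 floats per frame. `"bin"` is a compact binary
#' layout (magic string, integer dimensions, little-endian doubles) that
#' round-trips values bit-exactly.
#'
#' @param path file to read.
#' @param format `"csv"` or `"bin"`.
#' @param read_id label for the profile; defaults to the file name.
#' @return A [probability_profile()].
#' @seealso [write_profile()]
#' @examples
#' f <- system.file("extdata", "example_profile.csv", package = "pairconsensus")
#' p <- read_profile(f)
#' viterbi_decode(p)
#' @export
read_profile <- function(path, format = c("csv", "bin"), read_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(read_id))
    read_id <- sub("\\.[^.]*$", "", basename(path))
  if (format == "csv") {
    lines <- readLines(path)
    order <- PROFILE_ALPHABET
    if (length(lines) > 0L && grepl("^#", lines[1L])) {
      m <- regmatches(lines[1L], regexec("alphabet=([ACGT-]{5})", lines[1L]))[[1L]]
      if (length(m) == 2L) order <- strsplit(m[2L], "")[[1L]]
      lines <- lines[-1L]
    }
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0L) stop("profile file has no data rows: ", path)
    rows <- strsplit(lines, ",")
    nf <- lengths(rows)
    if (any(nf != 5L))
      stop(sprintf("parse error in %s: row %d has %d fields, expected 5",
                   path, which(nf != 5L)[1L], nf[nf != 5L][1L]))
    vals <- suppressWarnings(as.numeric(unlist(rows)))
    if (anyNA(vals)) {
      bad <- ceiling(which(is.na(vals))[1L] / 5)
      stop(sprintf("parse error in %s: non-numeric value in row %d", path, bad))
    }
    mat <- matrix(vals, ncol = 5L, byrow = TRUE)
  } else {
    con <- file(path, "rb")
    on.exit(close(con))
    magic <- readChar(con, 8L, useBytes = TRUE)
    if (!identical(magic, "CTCPROF1"))
      stop("parse error: ", path, " is not a binary profile (bad magic)")
    dims <- readBin(con, "integer", 2L, size = 4L, endian = "little")
    order <- strsplit(readChar(con, 5L, useBytes = TRUE), "")[[1L]]
    mat <- matrix(readBin(con, "double", dims[1L] * dims[2L], size = 8L,
                          endian = "little"),
                  nrow = dims[1L], ncol = dims[2L], byrow = TRUE)
  }
  probability_profile(mat, read_id = read_id, column_order = order)
}

#' Write a probability profile to disk
#'
#' @param profile a [probability_profile()].
#' @param path destination file.
#' @param format `"csv"` (text, 17 significant digits) or `"bin"`
#'   (bit-exact binary).
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path, format = c("csv", "bin")) {
  format <- match.arg(format)
  stopifnot(inherits(profile, "probability_profile"))
  m <- profile$probabilities
  if (format == "csv") {
    rows <- apply(m, 1L, function(r) paste(sprintf("%.17g", r), collapse = ","))
    writeLines(c("# alphabet=ACGT-", rows), path)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeChar("CTCPROF1", con, nchars = 8L, eos = NULL)
    writeBin(c(nrow(m), ncol(m)), con, size = 4L, endian = "little")
    writeChar("ACGT-", con, nchars = 5L, eos = NULL)
    writeBin(as.vector(t(m)), con, size = 8L, endian = "little")
  }
  invisible(path)
}

#' Reverse-complement a probability profile
#'
#' Places a complement-strand profile (e.g. the second read of a 1D2 pair)
#' on the template strand's coordinate system: frame order is reversed and
#' the base columns are swapped A<->T and C<->G; the blank column is
#' untouched. The operation is an involution.
#'
#' @param profile a [probability_profile()].
#' @return A [probability_profile()] of the same dimensions.
#' @export
reverse_complement_profile <- function(profile) {
  stopifnot(inherits(profile, "probability_profile"))
  m <- profile$probabilities[profile$T:1L, c("T", "G", "C", "A", "-"),
                             drop = FALSE]
  probability_profile(m, read_id = profile$read_id)
}

#' Reverse-complement a DNA string
#'
#' @param x character vector of sequences over A, C, G, T.
#' @return The reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

check_dna <- function(x, allow_empty = TRUE) {
  if (!is.character(x) || length(x) != 1L || is.na(x))
    stop("a DNA sequence must be a single character string")
  if (!allow_empty && nchar(x) == 0L) stop("sequence must be non-empty")
  if (grepl("[^ACGT]", x)) stop("sequence contains characters outside A,C,G,T")
  x
}

#' Write decode results to a FASTA file
#'
#' Standard multi-FASTA with 80-column line wrap. Each header carries the
#' read id and, when available, the decode log-probability as a comment
#' field (`logp=`).
#'
#' @param results a single decode result or a list of them (objects with
#'   `sequence` and optionally `log_prob`/`log_prob_combined` fields), or a
#'   named character vector of sequences.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(results, path) {
  if (inherits(results, "decode_result") || inherits(results, "pair_decode_result"))
    results <- list(results)
  lines <- character(0)
  for (k in seq_along(results)) {
    r <- results[[k]]
    if (is.character(r)) {
      id <- if (!is.null(names(results))) names(results)[k] else sprintf("seq%d", k)
      hdr <- paste0(">", id)
      s <- r
    } else {
      id <- if (!is.null(r$read_id)) r$read_id else sprintf("seq%d", k)
      lp <- if (!is.null(r$log_prob)) r$log_prob else r$log_prob_combined
      hdr <- if (is.null(lp)) paste0(">", id)
             else sprintf(">%s logp=%.6f", id, lp)
      s <- r$sequence
    }
    lines <- c(lines, hdr,
               if (nchar(s) > 0L)
                 substring(s, seq(1L, nchar(s), 80L),
                           pmin(seq(1L, nchar(s), 80L) + 79L, nchar(s))))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read sequences from a FASTA file
#'
#' @param path FASTA file.
#' @return Named character vector of sequences (names are the first
#'   whitespace-delimited token of each header).
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}
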