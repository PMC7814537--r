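# Guide alignment and alignment-envelope construction: the machinery that
# turns two preliminary basecalls into a band for the 2D consensus search.

#' Alignment scoring parameters
#'
#' Linear-gap global alignment scores and the half-width of the fixed
#' diagonal band (in DP cells around the length-rescaled diagonal).
#'
#' @param match match score (default 2).
#' @param mismatch mismatch score (default -1).
#' @param gap linear gap score (default -2).
#' @param band_half_width band radius in cells (default 100).
#' @return An object of class `align_params`.
#' @export
align_params <- function(match = 2, mismatch = -1, gap = -2,
                         band_half_width = 100L) {
  if (!(match > mismatch)) stop("`match` must exceed `mismatch`")
  if (!(gap < 0)) stop("`gap` must be negative")
  band_half_width <- as.integer(band_half_width)
  if (is.na(band_half_width) || band_half_width < 1L)
    stop("`band_half_width` must be a positive integer")
  structure(list(match = match, mismatch = mismatch, gap = gap,
                 band_half_width = band_half_width),
            class = "align_params")
}

#' Banded global (Needleman-Wunsch) alignment
#'
#' Global alignment with linear gap penalties, restricted to DP cells
#' `(i, j)` with `|i * (|b|/|a|) - j| <= band_half_width` — a fixed band
#' around the length-rescaled diagonal, so reads of unequal length remain
#' alignable. Whenever the unbanded optimum lies inside the band the result
#' equals full Needleman-Wunsch. A band too narrow to connect the matrix
#' corners raises an error rather than silently returning a worse path.
#'
#' @param a,b DNA sequence strings (possibly empty).
#' @param params an [align_params()].
#' @return An object of class `guide_alignment`: list with `columns` (a
#'   data frame with 1-based base indices `i`, `j`, `NA` for a gap, and the
#'   aligned characters), `score`, `matches`, `alignment_length` and the two
#'   input sequences.
#' @export
banded_global_align <- function(a, b, params = align_params()) {
  check_dna(a); check_dna(b)
  stopifnot(inherits(params, "align_params"))
  av <- strsplit(a, "")[[1L]]; bv <- strsplit(b, "")[[1L]]
  n <- length(av); m <- length(bv)
  w <- params$band_half_width; gp <- params$gap
  r <- if (n > 0L) m / n else 0
  lo <- pmax(0L, ceiling((0:n) * r - w))
  hi <- pmin(m, floor((0:n) * r + w))
  NEG <- -Inf
  S <- matrix(NEG, n + 1L, m + 1L)  # S[i+1, j+1] = best score ending at (i, j)
  S[1L, (lo[1L]:hi[1L]) + 1L] <- (lo[1L]:hi[1L]) * gp
  for (i in seq_len(n)) {
    js <- lo[i + 1L]:hi[i + 1L]
    for (j in js) {
      best <- NEG
      if (j > 0L) {
        sub <- if (av[i] == bv[j]) params$match else params$mismatch
        d <- S[i, j]
        if (d > NEG) best <- d + sub
      }
      up <- S[i, j + 1L]
      if (up > NEG) best <- max(best, up + gp)
      if (j > 0L) {
        lf <- S[i + 1L, j]
        if (lf > NEG) best <- max(best, lf + gp)
      }
      S[i + 1L, j + 1L] <- best
    }
  }
  if (!is.finite(S[n + 1L, m + 1L]))
    stop(sprintf(paste0("band of half-width %d cannot connect (0,0) to ",
                        "(%d,%d); widen `band_half_width`"), w, n, m))
  # traceback by re-deriving the move from stored scores
  i <- n; j <- m
  ii <- integer(0); jj <- integer(0)
  while (i > 0L || j > 0L) {
    here <- S[i + 1L, j + 1L]
    if (i > 0L && j > 0L) {
      sub <- if (av[i] == bv[j]) params$match else params$mismatch
      if (is.finite(S[i, j]) && here == S[i, j] + sub) {
        ii <- c(i, ii); jj <- c(j, jj); i <- i - 1L; j <- j - 1L
        next
      }
    }
    if (i > 0L && is.finite(S[i, j + 1L]) && here == S[i, j + 1L] + gp) {
      ii <- c(i, ii); jj <- c(NA_integer_, jj); i <- i - 1L
      next
    }
    ii <- c(NA_integer_, ii); jj <- c(j, jj); j <- j - 1L
  }
  cols <- data.frame(i = ii, j = jj,
                     a = ifelse(is.na(ii), "-", av[ifelse(is.na(ii), 1L, ii)]),
                     b = ifelse(is.na(jj), "-", bv[ifelse(is.na(jj), 1L, jj)]),
                     stringsAsFactors = FALSE)
  matches <- sum(!is.na(cols$i) & !is.na(cols$j) & cols$a == cols$b)
  structure(list(columns = cols, score = S[n + 1L, m + 1L],
                 matches = matches, alignment_length = nrow(cols),
                 a = a, b = b),
            class = "guide_alignment")
}

#' @export
print.guide_alignment <- function(x, ...) {
  cat(sprintf("<guide_alignment> %d columns, %d matches, score %.1f\n",
              x$alignment_length, x$matches, x$score))
  if (x$alignment_length > 0 && x$alignment_length <= 100) {
    cat(paste(x$columns$a, collapse = ""), "\n")
    cat(paste(ifelse(x$columns$a == x$columns$b & x$columns$a != "-", "|", " "),
              collapse = ""), "\n")
    cat(paste(x$columns$b, collapse = ""), "\n")
  }
  invisible(x)
}

#' Map each decoded base to its signal frame interval
#'
#' From a Viterbi label path, assigns every base of the collapsed sequence a
#' half-open frame interval `[start, end)` in 0-based frame coordinates. A
#' base's interval runs from its first emitting frame to the frame before the
#' next base's first emitting frame: trailing blanks attach to the preceding
#' base and leading blanks to the first base, so the intervals tile `[0, T)`.
#'
#' @param path character vector of per-frame labels (`"-"` = blank).
#' @return An object of class `sequence_signal_map`: data frame with columns
#'   `base`, `start`, `end`, plus attribute `frames` (= `T`). An all-blank
#'   path yields a zero-row map.
#' @export
path_to_signal_map <- function(path) {
  T <- length(path)
  if (!all(path %in% PROFILE_ALPHABET))
    stop("path labels must be in A, C, G, T, -")
  nonblank <- path != "-"
  starts <- which(nonblank &
                  (seq_along(path) == 1L | path != c("", path[-T])))
  if (length(starts) == 0L) {
    map <- data.frame(base = character(0), start = integer(0), end = integer(0))
  } else {
    k <- length(starts)
    map <- data.frame(base = path[starts],
                      start = c(0L, starts[-1L] - 1L),
                      end = c(starts[-1L] - 1L, T),
                      stringsAsFactors = FALSE)
  }
  structure(map, frames = T, class = c("sequence_signal_map", "data.frame"))
}

new_envelope <- function(lo, hi, T2) {
  structure(list(lo = as.integer(lo), hi = as.integer(hi),
                 T1 = length(lo), T2 = as.integer(T2)),
            class = "alignment_envelope")
}

validate_envelope <- function(env) {
  stopifnot(inherits(env, "alignment_envelope"))
  with(env, {
    if (length(lo) != T1 || length(hi) != T1)
      stop("envelope bound vectors must have length T1")
    if (any(lo < 0L) || any(hi > T2) || any(lo >= hi))
      stop("envelope bounds must satisfy 0 <= lo < hi <= T2")
    if (is.unsorted(lo) || is.unsorted(hi))
      stop("envelope bounds must be non-decreasing (monotone staircase)")
    if (lo[1L] != 0L) stop("envelope must cover cell (0, 0)")
    if (hi[T1] != T2) stop("envelope must cover cell (T1-1, T2-1)")
  })
  env
}

#' @export
print.alignment_envelope <- function(x, ...) {
  cat(sprintf("<alignment_envelope> %d x %d frames, %d cells (%.1f%% of full)\n",
              x$T1, x$T2, envelope_area(x),
              100 * envelope_area(x) / (as.numeric(x$T1) * x$T2)))
  invisible(x)
}

#' Full (unconstrained) alignment envelope
#'
#' @param T1,T2 frame counts of the two profiles.
#' @return An `alignment_envelope` admitting every `(t1, t2)` cell.
#' @export
full_envelope <- function(T1, T2) {
  validate_envelope(new_envelope(rep(0L, T1), rep(as.integer(T2), T1), T2))
}

#' Build an alignment envelope from a guide alignment
#'
#' Lifts the nucleotide-level guide alignment of the two Viterbi basecalls
#' into signal space: each aligned base pair `(i, j)` contributes the
#' rectangle `map1[i] x map2[j]`; a gap column extends the previous
#' rectangle along the gapped read's axis. Bounds are then dilated by
#' `padding` frames on each side, clipped, and repaired to a monotone
#' staircase (running max on `hi`; reversed running min on `lo`), with the
#' corner cells `(0,0)` and `(T1-1, T2-1)` forced into the envelope.
#'
#' @param map1,map2 [path_to_signal_map()] results for reads 1 and 2.
#' @param guide a [banded_global_align()] result for the two decoded
#'   sequences (read 1 as `a`, read 2 as `b`).
#' @param padding slack in frames added on every side (default 150,
#'   about 16 bases at 9 frames/base).
#' @return An `alignment_envelope` over `[0, T1) x [0, T2)`.
#' @export
build_envelope <- function(map1, map2, guide, padding = 150L) {
  stopifnot(inherits(guide, "guide_alignment"))
  padding <- as.integer(padding)
  if (is.na(padding) || padding < 0L) stop("`padding` must be non-negative")
  T1 <- attr(map1, "frames"); T2 <- attr(map2, "frames")
  if (nrow(guide$columns) == 0L && (nrow(map1) > 0L || nrow(map2) > 0L))
    stop("empty guide alignment cannot band non-empty reads")
  if (nrow(map1) != sum(!is.na(guide$columns$i)) ||
      nrow(map2) != sum(!is.na(guide$columns$j)))
    stop("guide alignment does not match the supplied signal maps")
  lo <- rep(Inf, T1); hi <- rep(-Inf, T1)
  cover <- function(r1, r2) {
    if (r1[2L] > r1[1L]) {
      idx <- (r1[1L] + 1L):r1[2L]  # 1-based rows for 0-based frames
      lo[idx] <<- pmin(lo[idx], r2[1L])
      hi[idx] <<- pmax(hi[idx], r2[2L])
    }
  }
  last1 <- c(0L, 1L); last2 <- c(0L, 1L)  # origin placeholder rectangles
  for (k in seq_len(nrow(guide$columns))) {
    i <- guide$columns$i[k]; j <- guide$columns$j[k]
    if (!is.na(i)) last1 <- c(map1$start[i], map1$end[i])
    if (!is.na(j)) last2 <- c(map2$start[j], map2$end[j])
    cover(last1, last2)
  }
  if (!all(is.finite(lo))) {  # rows never touched (degenerate maps)
    lo[!is.finite(lo)] <- 0; hi[!is.finite(hi)] <- T2
  }
  lo <- pmax(0L, as.integer(lo) - padding)
  hi <- pmin(as.integer(T2), as.integer(hi) + padding)
  lo[1L] <- 0L
  hi[T1] <- T2
  hi <- as.integer(cummax(hi))
  lo <- as.integer(rev(cummin(rev(lo))))
  lo <- pmin(lo, hi - 1L)
  validate_envelope(new_envelope(lo, hi, T2))
}

#' Number of admissible cells in an envelope
#'
#' The count of `(t1, t2)` dynamic-programming cells the envelope admits —
#' the quantity the envelope exists to shrink relative to the full
#' `T1 * T2` signal-space alignment.
#'
#' @param env an `alignment_envelope`.
#' @return Cell count (numeric, to avoid integer overflow).
#' @export
envelope_area <- function(env) {
  stopifnot(inherits(env, "alignment_envelope"))
  sum(as.numeric(env$hi) - env$lo)
}

#' Write an envelope as three-column text
#'
#' Columns are `t1`, `lo`, `hi` (0-based frames, half-open `[lo, hi)`).
#'
#' @param env an `alignment_envelope`.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_envelope <- function(env, path) {
  stopifnot(inherits(env, "alignment_envelope"))
  utils::write.table(data.frame(t1 = seq_len(env$T1) - 1L,
                                lo = env$lo, hi = env$hi),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
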