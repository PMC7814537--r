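# Ground-truthed simulator of softmax probability profiles. Emulates the
# shape of CTC basecaller output -- per-base dwells around 9 frames, blank
# frames between emissions, softmax rows concentrated on the true label --
# so every decoder can be exercised with a known answer and no real reads.

#' Simulation configuration
#'
#' @param frames_per_base_mean mean number of signal frames per base
#'   (default 9, the nanopore figure at 450 bases/s sampled at 4000 Hz).
#' @param frames_per_base_dispersion size parameter of the shifted
#'   negative-binomial dwell distribution (smaller = more overdispersed;
#'   default 3).
#' @param emission_concentration Dirichlet concentration added to the true
#'   label of each frame's softmax row; higher is cleaner (default 4,
#'   "moderate noise"). Ignored when `noiseless = TRUE`.
#' @param blank_fraction expected fraction of each dwell emitted as
#'   blank-dominant frames (default 0.4).
#' @param noiseless emit exact one-hot rows (the infinite-concentration
#'   limit).
#' @param seed integer seed making the draw reproducible; `NULL` uses the
#'   current RNG state.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(frames_per_base_mean = 9,
                              frames_per_base_dispersion = 3,
                              emission_concentration = 4,
                              blank_fraction = 0.4,
                              noiseless = FALSE,
                              seed = NULL) {
  if (frames_per_base_mean < 1) stop("`frames_per_base_mean` must be >= 1")
  if (emission_concentration <= 0) stop("`emission_concentration` must be > 0")
  if (blank_fraction < 0 || blank_fraction >= 1)
    stop("`blank_fraction` must be in [0, 1)")
  if (frames_per_base_dispersion <= 0)
    stop("`frames_per_base_dispersion` must be > 0")
  structure(list(frames_per_base_mean = frames_per_base_mean,
                 frames_per_base_dispersion = frames_per_base_dispersion,
                 emission_concentration = emission_concentration,
                 blank_fraction = blank_fraction,
                 noiseless = isTRUE(noiseless),
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "simulation_config")
}

#' Random DNA sequence
#'
#' @param n length in bases.
#' @return A string of `n` bases drawn uniformly from A,C,G,T.
#' @export
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

simulate_read_impl <- function(truth, cfg) {
  bases <- strsplit(truth, "")[[1L]]
  L <- length(bases)
  # dwell per base: shifted negative binomial, minimum one frame
  dwell <- 1L + stats::rnbinom(L, size = cfg$frames_per_base_dispersion,
                               mu = cfg$frames_per_base_mean - 1)
  nblank <- stats::rbinom(L, dwell - 1L, cfg$blank_fraction)
  # the collapse rule merges adjacent identical bases, so consecutive
  # identical bases must be separated by at least one blank frame
  rep_next <- c(bases[-L] == bases[-1L], FALSE)
  need <- rep_next & nblank == 0L
  dwell[need & dwell == 1L] <- 2L
  nblank[need] <- 1L
  path <- unlist(lapply(seq_len(L), function(i) {
    c(rep(bases[i], dwell[i] - nblank[i]), rep("-", nblank[i]))
  }), use.names = FALSE)
  T <- length(path)
  target <- match(path, PROFILE_ALPHABET)
  if (cfg$noiseless) {
    m <- matrix(0, T, 5L)
    m[cbind(seq_len(T), target)] <- 1
  } else {
    alpha <- matrix(0.2, T, 5L)
    alpha[cbind(seq_len(T), target)] <-
      0.2 + cfg$emission_concentration
    g <- matrix(stats::rgamma(T * 5L, shape = alpha), T, 5L)
    m <- g / rowSums(g)
  }
  structure(list(truth = truth,
                 profile = probability_profile(m),
                 true_path = path,
                 true_map = path_to_signal_map(path)),
            class = "simulated_read")
}

#' Simulate one read's probability profile
#'
#' Per base, a dwell is drawn from a shifted negative binomial (minimum one
#' frame); within the dwell each frame's softmax row is drawn from a
#' Dirichlet concentrated on the true base, with blank-dominant frames
#' inserted at rate `blank_fraction` (and always at least one blank between
#' consecutive identical bases, so the truth is reachable under the
#' merge-repeats collapse; blank frames sit at the end of a dwell, matching
#' the trailing-blank convention of [path_to_signal_map()]).
#'
#' @param truth non-empty DNA string the read derives from.
#' @param cfg a [simulation_config()].
#' @return An object of class `simulated_read`: list with `truth`, `profile`,
#'   `true_path` and `true_map`.
#' @export
simulate_read <- function(truth, cfg = simulation_config()) {
  check_dna(truth, allow_empty = FALSE)
  stopifnot(inherits(cfg, "simulation_config"))
  if (!is.null(cfg$seed))
    withr::with_seed(cfg$seed, simulate_read_impl(truth, cfg))
  else
    simulate_read_impl(truth, cfg)
}

#' @export
print.simulated_read <- function(x, ...) {
  cat(sprintf("<simulated_read> %d bases -> %d frames (%.2f frames/base)\n",
              nchar(x$truth), x$profile$T, x$profile$T / nchar(x$truth)))
  invisible(x)
}

#' Simulate a 1D2 read pair
#'
#' Two independent reads of the same underlying sequence. With
#' `as_complement = TRUE` the second read is generated from the reverse
#' complement of `truth` and its profile is stored in complement
#' orientation, as a real 1D2 complement-strand read would be; downstream,
#' [pair_decode_pipeline()] must then be called with
#' `complement_strand_2 = TRUE`.
#'
#' @param truth non-empty DNA string for the duplex.
#' @param cfg1 [simulation_config()] for read 1.
#' @param cfg2 configuration for read 2 (defaults to `cfg1`; give it a
#'   different `seed` to decorrelate the draws when seeds are used).
#' @param as_complement store read 2 on the complement strand.
#' @return List of class `simulated_pair` with `read1`, `read2`, `truth` and
#'   `as_complement`.
#' @export
simulate_pair <- function(truth, cfg1 = simulation_config(), cfg2 = cfg1,
                          as_complement = FALSE) {
  check_dna(truth, allow_empty = FALSE)
  r1 <- simulate_read(truth, cfg1)
  truth2 <- if (as_complement) revcomp(truth) else truth
  if (!is.null(cfg2$seed) && identical(cfg2$seed, cfg1$seed)) {
    # same seed for both reads would duplicate the noise; derive a distinct one
    cfg2$seed <- cfg2$seed + 1L
  }
  r2 <- simulate_read(truth2, cfg2)
  r1$profile$read_id <- "template"
  r2$profile$read_id <- if (as_complement) "complement" else "template2"
  structure(list(read1 = r1, read2 = r2, truth = truth,
                 as_complement = isTRUE(as_complement)),
            class = "simulated_pair")
}

#' Mean signal frames per base implied by pore kinetics
#'
#' DNA translocates at about 450 bases per second while the current is
#' sampled at 4000 Hz, so each base occupies on average
#' `sampling_hz / bases_per_second` frames -- about 9. Squaring that factor
#' gives the cost ratio of signal-level versus base-level alignment.
#'
#' @param sampling_hz signal sampling rate (default 4000).
#' @param bases_per_second translocation speed (default 450).
#' @return Frames per base (unrounded).
#' @export
frames_per_base <- function(sampling_hz = 4000, bases_per_second = 450) {
  if (sampling_hz <= 0 || bases_per_second <= 0)
    stop("rates must be positive")
  sampling_hz / bases_per_second
}
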