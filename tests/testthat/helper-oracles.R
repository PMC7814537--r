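# Independent oracles used across the suite. These enumerate label paths or
# candidate sequences directly and never share code with the recursions under
# test (apart from collapse_path, which is itself pinned by hand examples).

ALPHABET5 <- c("A", "C", "G", "T", "-")

# random row-stochastic profile via flat Dirichlet rows
rand_profile <- function(T, seed, concentration = 1) {
  set.seed(seed)
  g <- matrix(stats::rgamma(T * 5L, shape = concentration), T, 5L)
  probability_profile(g / rowSums(g), read_id = sprintf("rand%d", seed))
}

# all 5^T label paths of length T, as an integer matrix (one row per path)
# plus each path's collapsed sequence; cached per T
.path_cache <- new.env(parent = emptyenv())
enumerate_paths <- function(T) {
  key <- as.character(T)
  if (!is.null(.path_cache[[key]])) return(.path_cache[[key]])
  paths <- as.matrix(expand.grid(rep(list(1:5), T)))
  dimnames(paths) <- NULL
  coll <- apply(paths, 1L, function(pa) collapse_path(ALPHABET5[pa]))
  out <- list(paths = paths, collapsed = coll)
  .path_cache[[key]] <- out
  out
}

# per-path log products under a profile
path_log_products <- function(profile, paths) {
  lp <- log(profile$probabilities)
  out <- numeric(nrow(paths))
  for (t in seq_len(ncol(paths))) out <- out + lp[t, paths[, t]]
  out
}

# exact forward probability by brute-force path enumeration
bf_forward <- function(profile, sequence) {
  en <- enumerate_paths(profile$T)
  keep <- en$collapsed == sequence
  if (!any(keep)) return(-Inf)
  v <- path_log_products(profile, en$paths[keep, , drop = FALSE])
  m <- max(v)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(v - m)))
}

# every DNA string of length 0..L, shortest first then lexicographic
all_dna_upto <- function(L) {
  out <- ""
  for (k in seq_len(L)) {
    g <- expand.grid(rep(list(c("A", "C", "G", "T")), k))[, k:1, drop = FALSE]
    out <- c(out, do.call(paste0, g))
  }
  out
}

# exhaustive 1D argmax of forward_probability over sequences of length <= L
exhaustive_argmax <- function(profile, L = profile$T) {
  cands <- all_dna_upto(L)
  lp <- vapply(cands, function(s) forward_probability(profile, s), numeric(1))
  list(sequence = cands[which.max(lp)], log_prob = max(lp))
}

# exhaustive pair argmax of the summed forward log-probabilities
exhaustive_pair_argmax <- function(p1, p2, L = min(p1$T, p2$T)) {
  cands <- all_dna_upto(L)
  lp <- vapply(cands,
               function(s) forward_probability(p1, s) + forward_probability(p2, s),
               numeric(1))
  list(sequence = cands[which.max(lp)], log_prob = max(lp))
}

# unbanded Needleman-Wunsch score oracle (Biostrings, linear gaps)
nw_score_oracle <- function(a, b, match = 2, mismatch = -1, gap = -2) {
  sm <- matrix(mismatch, 4, 4,
               dimnames = list(c("A", "C", "G", "T"), c("A", "C", "G", "T")))
  diag(sm) <- match
  Biostrings::pairwiseAlignment(a, b, type = "global",
                                substitutionMatrix = sm,
                                gapOpening = 0, gapExtension = -gap,
                                scoreOnly = TRUE)
}

# does the envelope contain the whole true co-alignment (every base's
# read-1 frame paired with its full read-2 frame interval)?
envelope_covers_truth <- function(pair, env) {
  m1 <- pair$read1$true_map
  m2 <- pair$read2$true_map
  for (k in seq_len(nrow(m1))) {
    idx <- (m1$start[k] + 1L):m1$end[k]
    if (any(env$lo[idx] > m2$start[k]) || any(env$hi[idx] < m2$end[k]))
      return(FALSE)
  }
  TRUE
}

# envelope built from the simulation's ground truth (identity guide on the
# true sequence, true signal maps)
true_guide_envelope <- function(pair, padding) {
  g <- banded_global_align(pair$truth, pair$truth)
  build_envelope(pair$read1$true_map, pair$read2$true_map, g, padding = padding)
}
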