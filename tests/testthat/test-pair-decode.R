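test_that("duplicated evidence reproduces the single-read decode with doubled score", {
  one_hot <- matrix(0, 6, 5)
  one_hot[cbind(1:6, c(1, 5, 2, 2, 5, 3))] <- 1  # A - C C - G -> "ACCG"
  p <- probability_profile(one_hot)
  single <- beam_search_decode(p, 32)
  r <- pair_beam_search(p, p, full_envelope(6, 6), beam_width = 32)
  expect_identical(r$sequence, single$sequence)
  expect_equal(r$log_prob_combined, 2 * single$log_prob, tolerance = 1e-9)
  expect_equal(r$log_prob_combined, r$log_prob_1 + r$log_prob_2,
               tolerance = 1e-9)
})

test_that("pair beam search matches the exhaustive pair argmax on tiny profiles", {
  for (seed in c(101, 102, 103, 104, 105)) {
    p1 <- rand_profile(4, seed = seed)
    p2 <- rand_profile(4, seed = seed + 1000)
    r <- pair_beam_search(p1, p2, full_envelope(4, 4), beam_width = 4096)
    ex <- exhaustive_pair_argmax(p1, p2)
    expect_identical(r$sequence, ex$sequence)
    expect_equal(r$log_prob_combined, ex$log_prob, tolerance = 1e-9)
    # reported components equal the exact per-read forward probabilities
    expect_equal(r$log_prob_1, forward_probability(p1, r$sequence),
                 tolerance = 1e-6)
    expect_equal(r$log_prob_2, forward_probability(p2, r$sequence),
                 tolerance = 1e-6)
  }
})

test_that("pair decoding is symmetric in the two reads", {
  for (seed in c(111, 112)) {
    p1 <- rand_profile(5, seed = seed)
    p2 <- rand_profile(4, seed = seed + 500)
    a <- pair_beam_search(p1, p2, full_envelope(5, 4), beam_width = 4096)
    b <- pair_beam_search(p2, p1, full_envelope(4, 5), beam_width = 4096)
    expect_identical(a$sequence, b$sequence)
    expect_equal(a$log_prob_combined, b$log_prob_combined, tolerance = 1e-9)
    expect_equal(a$log_prob_1, b$log_prob_2, tolerance = 1e-9)
  }
})

test_that("dimension mismatches and bad beam widths are refused", {
  p1 <- rand_profile(5, 1); p2 <- rand_profile(4, 2)
  expect_error(pair_beam_search(p1, p2, full_envelope(5, 5)), "frames")
  expect_error(pair_beam_search(p1, p2, full_envelope(5, 4), beam_width = 0),
               "positive")
})

test_that("noiseless pipeline recovers the truth exactly, on both strands", {
  truth <- withr::with_seed(120, random_dna(50))
  cfgs <- list(simulation_config(seed = 121, noiseless = TRUE),
               simulation_config(seed = 122, noiseless = TRUE))
  pr <- simulate_pair(truth, cfgs[[1]], cfgs[[2]])
  res <- pair_decode_pipeline(pr$read1$profile, pr$read2$profile)
  expect_identical(res$sequence, truth)
  expect_equal(compute_identity(truth, res$sequence)$identity, 1.0)

  prc <- simulate_pair(truth, cfgs[[1]], cfgs[[2]], as_complement = TRUE)
  resc <- pair_decode_pipeline(prc$read1$profile, prc$read2$profile,
                               complement_strand_2 = TRUE)
  expect_identical(resc$sequence, truth)
})

test_that("a single-frame blank second read degenerates to read 1's argmax", {
  # one-hot read 1: every candidate's combined mass is zero (read 2 cannot
  # emit bases, read 1 cannot emit ""), and the tie rules hand the decision
  # to read 1's own beam
  p1 <- simulate_read("ACGT",
                      simulation_config(seed = 130, noiseless = TRUE))$profile
  blank <- probability_profile(matrix(c(0, 0, 0, 0, 1), 1, 5))
  r <- pair_beam_search(p1, blank, full_envelope(p1$T, 1), beam_width = 64)
  expect_identical(r$sequence, beam_search_decode(p1, 64)$sequence)

  # with a soft read 1 the empty sequence is the objective-consistent optimum:
  # it is the only sequence with non-zero probability under both reads
  soft <- rand_profile(3, seed = 131)
  r2 <- pair_beam_search(soft, blank, full_envelope(3, 1), beam_width = 256)
  expect_identical(r2$sequence, "")
  expect_equal(r2$log_prob_1, forward_probability(soft, ""), tolerance = 1e-9)
  expect_equal(r2$log_prob_2, 0, tolerance = 1e-12)
})

test_that("banding with a truth-covering envelope preserves the decode", {
  # where the posterior mode is well resolved, restricting the search to an
  # envelope that contains the true co-alignment cannot change the answer
  for (s in 1:3) {
    pr <- simulate_pair(random_dna(25),
                        simulation_config(seed = 140 + s, noiseless = TRUE),
                        simulation_config(seed = 150 + s, noiseless = TRUE))
    env <- true_guide_envelope(pr, padding = 10L)
    expect_true(envelope_covers_truth(pr, env))
    T1 <- pr$read1$profile$T; T2 <- pr$read2$profile$T
    band <- pair_beam_search(pr$read1$profile, pr$read2$profile, env)
    full <- pair_beam_search(pr$read1$profile, pr$read2$profile,
                             full_envelope(T1, T2))
    expect_identical(band$sequence, full$sequence)
    expect_identical(band$sequence, pr$truth)
  }
})

test_that("an implausible guide alignment triggers the fallback policy", {
  # two unrelated reads: guide identity collapses below the 0.3 threshold
  pr1 <- simulate_read(withr::with_seed(160, random_dna(20)),
                       simulation_config(seed = 161, noiseless = TRUE))
  pr2 <- simulate_read(withr::with_seed(162, paste(rep(c("C", "A"), 15),
                                                   collapse = "")),
                       simulation_config(seed = 163, noiseless = TRUE))
  expect_warning(
    pair_decode_pipeline(pr1$profile, pr2$profile,
                         min_guide_identity = 0.95),
    "full envelope")
  expect_error(
    pair_decode_pipeline(pr1$profile, pr2$profile,
                         min_guide_identity = 0.95,
                         low_identity_action = "error"),
    "pair")
})
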