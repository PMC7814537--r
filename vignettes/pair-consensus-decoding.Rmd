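---
title: "Pair consensus decoding of CTC basecaller profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pair consensus decoding of CTC basecaller profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pairconsensus)
```

## The problem

Nanopore sequencers read single DNA molecules by measuring the ionic current
through a protein pore as the strand translocates. A neural network
basecaller trained with Connectionist Temporal Classification (CTC) turns the
current time series into, for each signal frame, a softmax distribution over
the four bases plus a *blank* gap symbol. That `T x 5` matrix — the
**probability profile** — defines a distribution over basecalled sequences:

$$P(\ell \mid y) \;=\; \sum_{\pi\,:\,\mathcal{B}(\pi) = \ell}\; \prod_{t=1}^{T} p_t(\pi_t),$$

where the sum runs over all frame-level label paths $\pi$ that *collapse* to
$\ell$ under the CTC rule $\mathcal{B}$ (merge runs of identical non-blank
labels, then delete blanks). Decoding — finding the modal $\ell$ — is
intractable exactly, so Viterbi (best single path) and prefix beam search are
used in practice.

When a duplex is read twice — template strand then complement strand, as in
the 1D² protocol — two profiles $y_1, y_2$ describe the same sequence.
Under a flat prior over sequences and independent reads, the maximum a
posteriori consensus is

$$\ell^\ast = \arg\max_\ell\; P(\ell \mid y_1)\, P(\ell \mid y_2),$$

and finding it is the purpose of this package. Working at the level of the
basecaller's probabilities (rather than reconciling two already-called
sequences) lets the strong evidence in one read rescue ambiguous frames in
the other.

## The algorithm

1. **Preliminary basecalls.** Each profile is Viterbi-decoded. With
   per-frame posteriors and no transition model, the best path is the
   per-frame argmax (ties broken in alphabet order A < C < G < T < blank),
   collapsed to a sequence. This also yields a **sequence-to-signal map**:
   each base's half-open interval of frames, with trailing blanks attached
   to the preceding base and leading blanks to the first.
2. **Guide alignment.** The two basecalls are aligned globally with a
   Needleman–Wunsch restricted to a fixed band around the length-rescaled
   diagonal (cell $(i,j)$ admissible iff $|j - i\,|b|/|a|| \le w$), linear
   gap penalties. Nanopore reads span orders of magnitude in length, and the
   band keeps the DP matrix linear in read length; whenever the unbanded
   optimum lies inside the band the two solutions coincide, and a band that
   cannot connect the matrix corners is reported as an error, never as a
   silently suboptimal alignment.
3. **Alignment envelope.** Each aligned base pair $(i,j)$ contributes the
   rectangle `map1[i] x map2[j]` in the $(t_1, t_2)$ frame plane; gap
   columns extend the previous rectangle along the gapped read's axis. The
   union of rectangles is dilated by a configurable padding, clipped, and
   repaired to a monotone staircase stored as one `[lo, hi)` interval per
   $t_1$ row. At ~9 frames per base, aligning raw signal costs $(9T)^2$
   steps against $T^2$ for basecalls — an 81-fold factor — which is what
   the envelope claws back: on simulated pairs above 2000 frames the
   envelope at padding 10 covers ~1–3% of the full plane.
4. **Banded 2D beam search.** Beams are sequence prefixes. Each prefix
   carries CTC prefix-forward masses (blank-ending and non-blank-ending,
   in log space with log-sum-exp throughout) for *both* reads: scalars for
   read 1, advanced as $t_1$ sweeps forward, and a per-frame vector over
   read 2, computed lazily up to the envelope's `hi(t1)` and excluding mass
   below the envelope's `lo` at the prefix's creation time. A prefix is
   scored by its read-1 mass times its best read-2 mass inside the
   envelope's current row; the top `beam_width` prefixes survive each step.
   The consensus is the complete prefix maximizing the summed final log
   masses, reported with its two per-read components.

Any frame schedule with the property that the search is exact under a full
envelope and an adequate beam is acceptable here; this one was chosen
because read-2 vectors are pure functions of the prefix string (so they are
computed once at prefix creation and shared), memory stays bounded by the
beam and its ancestry, and exactness under a full envelope is easy to show:
with `beam_width` at least the number of distinct prefixes, no pruning
occurs and every final mass is the exact CTC forward probability. The test
suite verifies this against exhaustive enumeration.

## Tunable parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `beam_width` | 25 | prefixes | search breadth; larger converges to exact |
| `match`, `mismatch`, `gap` | 2, −1, −2 | score | guide alignment (linear gaps) |
| `band_half_width` | 100 | DP cells | diagonal band of the guide alignment |
| `padding` | 150 | frames | envelope dilation, ~16 bases at 9 frames/base |
| `min_guide_identity` | 0.3 | fraction | below it the reads are not treated as a pair |

The low-identity fallback either widens to the full envelope (sensible at
desk scale) or refuses (sensible for long reads, where a full envelope is
the quadratic cost the method exists to avoid).

## The simulator

Real acceptance data for this method would be thousands of 1D² read pairs
plus a trained network; neither ships here. Instead `simulate_read()`
emulates the *shape* of CTC output with known ground truth:

* **Dwell**: per base, `1 + NegBinomial(mean = 8, size = 3)` frames —
  matching the ~9 frames/base of a 450 bases/s translocation sampled at
  4000 Hz, with overdispersion, since real dwell times are far from
  geometric.
* **Emission**: each frame's softmax row is Dirichlet-distributed with
  concentration `0.2 + emission_concentration` on the frame's true label
  and 0.2 elsewhere; `emission_concentration = 4` (the "moderate noise"
  default used in the improvement study) gives raw per-frame accuracy
  around 85% and single-read basecall identities in the 70–85% range,
  deliberately on the noisy side of real basecallers so the consensus gain
  is visible at short simulated lengths.
* **Blanks**: each dwell ends in `Binomial(dwell − 1, 0.4)` blank-dominant
  frames, and consecutive identical bases are always separated by at least
  one blank so the truth is reachable under the merge-repeats collapse —
  a simulator convention, not a biological claim.

What the simulator does **not** reproduce: sequence-dependent (k-mer) error
structure, homopolymer length ambiguity, correlated noise between the two
strands of a duplex, chimeric or truncated reads, and basecaller
miscalibration. Passing tests therefore demonstrate algorithmic
correctness and the qualitative consensus gain, not field accuracy numbers
on real flowcells.

## Study conditions and what the package computes

The shipped checks (see `scripts/acceptance.R` in the source repository)
recompute, from scratch at fixed seeds:

* the analytic 9 frames/base and 81× signal-vs-base alignment cost figures;
* exactness of `beam_search_decode()` (width 4096) and
  `forward_probability()` against exhaustive enumeration on 50 small
  profiles, and of `pair_beam_search()` under a full envelope on 20 small
  profile pairs;
* normalization of the forward distribution ($\sum_\ell P(\ell\mid y) = 1$);
* equality of the banded aligner with unbanded Needleman–Wunsch
  (independent implementation) on 100 random pairs when the band covers;
* exact recovery (identity 1.0) of noiseless simulated pairs up to 200
  bases, on both strand orientations;
* the consensus improvement on 200 moderate-noise pairs of 40-base
  sequences — sizes chosen so the whole batch runs in minutes on one core;
  the margin is insensitive to length.

## Numerical and design choices

* All mass arithmetic is in natural-log space with log-sum-exp; exact zeros
  are `-Inf` sentinels. Profiles are stored in probability space on disk.
* Column order on disk is declared in the file header (`# alphabet=...`),
  defaulting to A, C, G, T, blank, because basecallers disagree on label
  order and a silent mismatch would corrupt every downstream number.
* Ties are broken deterministically everywhere: alphabet order, then
  shorter sequence, then lexicographic. Determinism is load-bearing for the
  oracle-equivalence tests.
* Rows whose sums drift from 1 by at most 1e-6 are renormalized on load;
  larger deviations are rejected with the offending row index. Rows already
  summing to 1 at double precision are left untouched so binary round-trips
  are bit-exact.
* The collapse rule is standard CTC (merge repeats, then drop blanks); a
  drop-blanks-only switch exists for networks trained without repeat
  merging, but is non-default.
* Degenerate inputs are defined, not accidental: an empty basecall skips
  envelope construction (full envelope), an all-blank path yields an empty
  signal map, and a read that cannot emit any base leaves the consensus to
  the other read's beam via the tie rules.

## Known limitations

* Envelope banding interacts with beam pruning: at heavy noise the banded
  and full-envelope searches are two different heuristics and can return
  different, similarly-scoring sequences (the banded one is often
  *better*, since the envelope focuses pruning on time-consistent
  prefixes). Strict banded-equals-full behaviour holds when the posterior
  mode is well resolved, and that is how it is tested.
* The per-creation cost of a prefix's read-2 vector scales with the
  envelope's `hi(t1)`, not with the row width `hi − lo`, so the realized
  speed-up is smaller than the envelope-area ratio suggests; the area
  ratio remains the right measure of the *search-space* restriction.
* Scores are unnormalized sums of the two per-read log masses; no
  length or read-count normalization is applied before comparison.
* Consensus of more than two reads, raw-signal ingestion, and
  transition-prior or language-model rescoring are out of scope.
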