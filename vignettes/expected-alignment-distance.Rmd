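---
title: "Measuring the reliability of pairwise protein alignments"
author: "marginalign"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the reliability of pairwise protein alignments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(marginalign)
```

## The problem

A pairwise alignment is a hypothesis about which residues of two protein
sequences descend from the same ancestral position. Alignment programs print
one alignment, but the posterior over alignments can be broad: as sequences
diverge, many alignments become nearly as plausible as the best one, and any
single reported alignment becomes an unreliable statement of homology.
`marginalign` quantifies that unreliability directly. Instead of scoring one
alignment, it weights *every* alignment of the pair by its posterior
probability and computes the exact expectation of a path distance to a fixed
reference alignment (typically one derived from structure superposition,
which is far better conserved than sequence).

## The probabilistic model

**Sequence model.** Matched residue pairs are scored by a time-parameterized
Markov substitution model: a 20x20 row-stochastic matrix `M` for one unit of
Markov time, with stationary distribution `pi`. At divergence time `t` the
joint probability of observing amino acids `a, b` in a matched column is
`pi[a] * M^t[a, b]`; unmatched (inserted or deleted) residues are charged a
time-independent 20-nomial, by default `pi`. Fractional powers `M^t` are
computed by eigendecomposition; integer powers by repeated squaring; tiny
negative entries from round-off are clamped and rows renormalized.
Time-reversibility is never assumed by the algorithms — only
row-stochasticity is enforced — though the bundled matrices happen to be
reversible, which gives monotone expected-change curves for free.

**Alignment model.** The alignment itself is generated by a three-state
machine over match/insert/delete with a per-step stop probability `rho`, so
an alignment's joint probability with the data is

    Pr(A, <S,T>) = phi[q1] * prod Pr(q_k+1 | q_k) * rho * prod emissions,

and its two-part message length is `I(A, <S,T>) = -log2 Pr(A, <S,T>)` bits.
Three quantities summarize a pair:

* `I(A*, <S,T>)` — the minimum two-part message length over alignments
  (Viterbi), with its biased divergence estimate `time_optimal`;
* `I_marginal(<S,T>) = -log2 sum_A Pr(A, <S,T>)` — the marginal evidence
  that the sequences are related at all (forward algorithm), with the
  unbiased `time_marginal`;
* `NULL(<S,T>)` — the null encoding of both sequences independently: a
  universal integer code for each length plus the 20-nomial for the
  residues.

The compression gains `delta_optimal = NULL - I(A*)` and
`delta_marginal = NULL - I_marginal` are log-posterior-odds tests: a
hypothesis with `delta <= 0` is rejected. The marginal can detect a
relationship when no single alignment is significant.

**Divergence inference.** Both times are inferred by minimizing the
corresponding message length over an integer grid on `[1, 500]` followed by
golden-section refinement inside the one-step bracket; ties resolve to the
smallest time, and refinement is discarded unless it strictly improves the
objective, so inference is deterministic.

## The default machine, and why it is shaped this way

The exact functional dependence of the published three-state machines on
Markov time is defined in prior work we deliberately do not re-derive; the
machine here is an explicit stand-in behind a pluggable interface
(`alignment_machine(transition_fn = ...)` replaces it wholesale). The
default is parameterized by a gap-open probability

    g(t) = g_max * (1 - exp(-t / tau)) * logistic((t - t0) / s)

with `g_max = 0.08`, `tau = 50`, `t0 = 200`, `s = 100`: gaps are essentially
absent at vanishing divergence (so identical sequences align all-match),
rise smoothly, and saturate near 8% per move in the midnight zone. Gap-state
occupancy is `r = 2.5` times the open probability (mean indel length around
two to three residues), a fraction `chi = 0.1` of gap flow crosses directly
between insert and delete, and the stop probability `rho = 0.002` encodes a
prior mean alignment length of 500 columns.

Two structural choices matter more than the numbers:

* **Detailed balance with the begin distribution equal to the machine's
  stationary distribution `phi(t)`.** With this pairing, the probability of
  every alignment path is invariant under simultaneous reversal of both
  sequences. Consequences: the marginal of the reversed pair equals the
  marginal of the pair exactly, and the suffix marginals needed by the
  probability landscape can be computed as a forward pass over the reversed
  pair, making the landscape's corner cells equal `I_marginal` exactly
  rather than approximately. A begin-at-match convention was the obvious
  alternative; it breaks exact reversibility for no compensating benefit.
* **Self-delimiting alignment messages.** The stop probability terminates
  the alignment message, so no separate length code is needed there; the
  null message carries explicit universal integer codes
  (`log2(2.865064) + log2 n + log2 log2 n + ...`) for the two sequence
  lengths. The cost of stating `t` itself is omitted from both competing
  messages — it is an identical additive constant and cancels from every
  `delta`. Absolute bit values therefore depend on these code choices, and
  published absolute bit tables are treated as a calibration surface, not as
  test oracles.

## The bundled substitution models

`bundled_model()` ships four matrices (`MMLSUM`, `PAM`, `BLOSUM`, `VTML`
"like"). They are *synthetic*: reversible GTR-style rate matrices built from
physicochemical-class exchangeabilities (aliphatic, aromatic, polar, basic,
acidic, plus slow-exchanging C, G, P) over a standard amino-acid
composition, differing between the four files in composition perturbations
and exchangeability sharpness. Each is calibrated — before any package test
was written against it — so that its expected-%-change curve

    expected_change(t) = 100 * (1 - sum_a pi[a] * M^t[a, a])

follows the published divergence scale for this model family: about 1% at
`t = 1`, at most 71% at `t = 150` (the daylight boundary, enforced as a hard
constraint during the fit), and approaching 92% by `t = 500`. The generator
script is `tools/make_models.R`; the files carry `# synthetic` headers.
These stand-ins reproduce the *scale* of the published models, not their
entries.

## The inter-alignment distance

An alignment is a source-to-sink path in the `(|S|+1) x (|T|+1)` grid. Every
path crosses each skew diagonal `k = i + j` exactly once; recording the
proper diagonal `j - i` of each crossing gives a profile `pi_k(A)`, and

    distance(A1, A2) = sum_k | pi_k(A1) - pi_k(A2) |

is an L1 metric on paths that measures the area-like separation between
them, not merely column identity. A match move crosses two skew diagonals at
once, both at the move's constant proper diagonal — this is why the match
recurrence below carries two width terms. Distances are normalized by
`|S| + |T|`, the maximum alignment length, for cross-pair comparability.
Under this definition the largest possible normalized distance is
`2|S||T| / (|S| + |T|)`, attained by the two opposite corner-hugging paths.

## The expected distance and its dynamic program

The reliability statistic is

    E[distance(A, A_ref)] = sum_A Pr(A | <S,T>) * distance(A, A_ref),

computed exactly in `O(|S||T|)` despite the factorial number of alignments.
Three matrices `EADm`, `EADi`, `EADd` memoize, per ending state, the
expected distance mass of all prefix alignments weighted by their
unnormalized joint probabilities; each cell adds the transition-propagated
mass of its three predecessors plus its own component marginal times the new
width terms (`delta` at skew `i+j-1` and `i+j` for a match, at `i+j` for a
gap), and the final expectation divides the sink total by the marginal.

Numerically the package implements the recurrences in an equivalent
conditional-expectation form: it carries `R_state = EAD_state / F_state`,
the expected distance conditional on reaching a cell in a state, so each
update is a convex combination of predecessor `R` values (weights
proportional to forward mass times transition probability, which are
invariant to any per-cell rescaling) plus the width increment. The forward
masses themselves are kept in linear space with per-row max rescaling. This
removes all underflow bookkeeping: expectations of sums do not commute with
log space, while the ratio form is unconditionally stable. Equivalence to
the direct recurrences is enforced in the test suite by brute-force
enumeration over all alignments of small pairs at 1e-9 relative tolerance.

`expected_distance_profile()` decomposes the same expectation by skew
diagonal using per-state forward and backward passes
(posterior occupancy times width, with the match move's first crossing
attributed to its own diagonal), which both localizes sequence/reference
disagreement and provides a second, independent route to the total.

**Degenerate inputs and conventions.** Cells whose entire forward mass
underflows to zero relative to their row maximum carry negligible posterior;
their conditional expectations are defined as zero and cannot contaminate
the result because their downstream weights are the same zeros. Viterbi ties
prefer match over delete over insert. Empty sequences are rejected at
construction. Ambiguity codes B/Z/U/O/J resolve to D/E/C/K/L; `X` is encoded
through an augmented emission slot carrying its stationary-expected
probabilities; strict mode rejects all of them. Reference alignments with a
column gapped in both sequences are rejected in strict mode and dropped with
a warning otherwise.

## Sampling validation

`sample_alignments()` draws alignments with probability exactly equal to
their posterior by stochastic traceback over the forward matrices (at each
step the predecessor is drawn proportional to forward mass times the
connecting transition; per-cell normalization makes row rescaling
irrelevant). The sampler is untempered and seeded explicitly; R's RNG state
is saved and restored around each call. `empirical_expected_distance()`
averages sampled distances to the reference — the Monte-Carlo counterpart
used to validate the exact dynamic program, mirroring a thousand-sample
check at `O(n^-1/2)` convergence.

## Divergence zones and survey summaries

`classify_zone()` partitions inferred times at 150/250/350 Markov-time
units into daylight, twilight, midnight and beyond-inference zones; each
upper boundary is inclusive (the published ranges are written with
overlapping endpoints, so a convention had to be fixed and documented).
`compression_group()` splits pairs by `delta` signs (group1:
`delta_optimal > 0`; group2: `delta_optimal <= 0 < delta_marginal`; group3:
`delta_marginal <= 0`). `quartile_summary()` bins records by rounded integer
`time_marginal` and reports per-bin Q1/Q2/Q3 of the normalized expected
distance (linear-interpolation quantiles, R type 7) plus the cumulative
percentage of pairs — the desk-scale analogue of the published
million-pair survey figures.

## What the synthetic generator does and does not emulate

`evolve_pair()` samples a pair from exactly the generative process the
likelihood scores: a state string from the machine at the true time
(transitions renormalized without stop, continuing until both sequences
reach the requested ancestor scale), matched pairs from the joint
`pi[a] * M^t[a, b]`, gap residues from the stationary 20-nomial. The
ancestor composition is stationary, so the observed mismatch fraction in
matched columns is an unbiased estimate of `expected_change(t)`, and indel
lengths are geometric as implied by the machine — there is no empirical
indel-length distribution, no rate heterogeneity across sites, no
composition bias, and no structural constraint. Passing recovery tests on
this generator therefore demonstrates internal consistency of model,
inference and distance machinery — not performance on real proteins, where
model misspecification adds error the survey itself is designed to expose.

`recovery_experiment()` re-infers `time_marginal` for replicate simulated
pairs and reports median and IQR per true time, plus the median normalized
expected distance to the true alignment. Its default problem sizes —
ancestor length 200, fifty replicates per time point, a step-5 scan grid
with golden-section refinement — were chosen as the smallest configuration
whose medians are stable across seeds; the step-5 scan loses essentially
nothing because the refined bracket restores sub-grid resolution.

## Known limitations

* Absolute message lengths depend on the package's own code choices
  (universal integer code, stop probability, omitted time-statement cost);
  only differences and trends are comparable across implementations.
* The default machine is a documented stand-in; inferred times shift with
  its parameters (`time` arguments on every entry point allow sensitivity
  analysis), though the zone partition itself is a property of the time
  scale, which the bundled models pin by calibration.
* The expectation is taken against a single fixed reference alignment;
  distances between two alignment *distributions* are out of scope.
* Pairwise comparison only: no database search heuristics, no structure
  parsing — reference alignments arrive as gapped FASTA from external
  structure-alignment tools.
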