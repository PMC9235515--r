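# marginalign

How much should you trust a pairwise protein sequence alignment? A single
reported alignment is one hypothesis drawn from a space that grows
factorially with sequence length, and as two proteins diverge, the posterior
over that space flattens until no individual alignment deserves belief.
`marginalign` is an R package for quantifying exactly this: it compares
protein sequence pairs under a minimum message length (MML) framework with
time-parameterized Markov substitution models, infers how far the pair has
diverged, and — its central statistic — computes the **exact
posterior-weighted expected distance between all sequence alignments of the
pair and a fixed reference alignment** (typically derived from structure),
in `O(|S||T|)` time. It is aimed at anyone who consumes pairwise alignments
downstream — homology modeling, evolutionary analysis, benchmark
construction — and needs to know when residue-level correspondences are
trustworthy, cautionary, or meaningless.

## The statistics it computes

For a pair `<S,T>` and an alignment `A` (a path of match/insert/delete
states), the two-part message length is
`I(A, <S,T>) = -log2 Pr(A, <S,T>)` bits, with matched residues priced by a
substitution model `pi[a] * M^t[a,b]` at Markov time `t` and gaps by a
20-nomial. The package reports:

* `I(A*, <S,T>)` and `time_optimal` — the optimal (Viterbi) alignment and
  its biased divergence estimate;
* `I_marginal = -log2 sum_A Pr(A, <S,T>)` and `time_marginal` — the
  marginal evidence of relatedness over *all* alignments (forward
  algorithm) and its unbiased divergence estimate;
* `delta_optimal`, `delta_marginal` — compression gains against the null
  (independent encoding of both sequences); `delta <= 0` rejects;
* the expected inter-alignment distance

  `E[distance(A, A_ref)] = sum_A Pr(A | <S,T>) * distance(A, A_ref)`

  where `distance` sums, over the skew diagonals of the alignment grid, the
  absolute difference of the two paths' proper-diagonal crossings — an L1
  metric on paths — normalized by `|S| + |T|`. An exact three-matrix dynamic
  program evaluates the factorially large sum in quadratic time; a
  posterior stochastic-traceback sampler provides the Monte-Carlo
  cross-check;
* a divergence-zone call from `time_marginal`: daylight `[0, 150]`
  (sequence alignments track structure closely), twilight `(150, 250]`
  (handle with caution), midnight `(250, 350]` (sequence evidence largely
  gone), beyond `> 350`.

Four bundled substitution models (`MMLSUM`, `PAM`, `BLOSUM`, `VTML`
"like") are synthetic reversible stand-ins calibrated to the published
divergence scale (about 1% expected change at `t = 1`, at most 71% at
`t = 150`, about 92% at `t = 500`); see `tools/make_models.R` and the
vignette for the construction.

## A worked example

```r
library(marginalign)
model   <- bundled_model("MMLSUM")
machine <- alignment_machine()

# a related pair simulated at known divergence, with its true alignment kept
sim  <- evolve_pair(length = 120, time = 180, model, machine, seed = 42)
pair <- sim$pair

res <- mml_compare(pair, model, machine, keep_forward = FALSE)
res
#> mml_comparison 'sim_t180_seed42' (|S|=126, |T|=120)
#>   null      :   1047.1 bits
#>   optimal   :   1041.6 bits (delta +5.5, time 154.1)
#>   marginal  :   1020.1 bits (delta +27.0, time 165.8)

classify_zone(res$time_marginal)
#> [1] twilight
expected_change(model, res$time_marginal)
#> [1] 73.8  (percent of residues expected to have changed)

ead <- expected_alignment_distance(pair, sim$true_alignment, model, machine,
                                   time = res$time_marginal)
ead$normalized
#> [1] 1.17

emp <- empirical_expected_distance(pair, sim$true_alignment, model, machine,
                                   time = res$time_marginal, n = 1000, seed = 1)
c(emp$mean, emp$se)
#> [1] 1.177 0.014
```

Reading the output: the pair was generated in the twilight zone, and the
statistics show exactly the twilight signature — the single optimal
alignment barely beats the null (`delta_optimal = +5.5` bits) while the
marginal over all alignments is decisively significant
(`delta_marginal = +27.0` bits), so the *relationship* is detectable even
though any individual alignment is shaky. The expected distance of the
posterior alignment ensemble from the true alignment is 1.17 width units
per possible column — far from zero, i.e. the reported alignment should not
be trusted residue by residue — and the 1000-sample empirical estimate
(1.177 ± 0.014) confirms the exact computation.

A thin command-line interface over the same functions ships in
`inst/cli/marginalign.R` (subcommands `compare`, `ead`, `sample`,
`landscape`, `zones`, `classify`, `simulate`, `recover`).

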