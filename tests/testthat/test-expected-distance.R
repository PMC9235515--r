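test_that("the EAD dynamic program reproduces the enumeration oracle exactly", {
  mod <- test_model(); mach <- test_machine()
  set.seed(909)
  for (k in 1:40) {
    m <- sample(1:5, 1); n <- sample(1:5, 1)
    p <- sequence_pair(random_residues(m), random_residues(n))
    tt <- runif(1, 2, 450)
    alns <- enumerate_alignments(m, n)
    ref <- pairwise_alignment(sample(alns, 1), m, n)
    oracle <- enum_ead(p, ref, mod, mach, tt)
    got <- expected_alignment_distance(p, ref, mod, mach, time = tt)
    expect_equal(got$raw, oracle$raw, tolerance = 1e-9)
    expect_equal(got$normalized, oracle$raw / (m + n), tolerance = 1e-9)
    # the expectation is bracketed by the extreme distances
    expect_gte(got$raw, min(oracle$distances) - 1e-9)
    expect_lte(got$raw, max(oracle$distances) + 1e-9)
  }
})

test_that("a reference holding all posterior mass has zero expected distance", {
  mod <- test_model(); mach <- test_machine()
  p <- sequence_pair("ARNDCQEG", "ARNDCQEG")
  ref <- pairwise_alignment(strrep("m", 8), 8, 8)
  got <- expected_alignment_distance(p, ref, mod, mach, time = 0.05)
  expect_lt(got$normalized, 1e-4)
})

test_that("moving the reference away from the posterior mode increases the expectation", {
  mod <- test_model(); mach <- test_machine()
  p <- sequence_pair("ARNDCQ", "ARNDCQ")
  refs <- list(strrep("m", 6),          # the mode itself
               "immmmmd",               # one cell off the diagonal
               "iimmmmdd",              # two cells off
               paste0(strrep("i", 6), strrep("d", 6)))  # corner-hugging
  e <- vapply(refs, function(st) {
    a <- pairwise_alignment(st, 6, 6)
    expected_alignment_distance(p, a, mod, mach, time = 10)$raw
  }, numeric(1))
  expect_true(all(diff(e) > 0))
})

test_that("the reference alignment must belong to the pair", {
  mod <- test_model(); mach <- test_machine()
  p <- sequence_pair("ARND", "ARND")
  expect_error(expected_alignment_distance(p, pairwise_alignment("mmm", 3, 3),
                                           mod, mach, time = 10),
               "inconsistent")
})

test_that("the per-skew-diagonal profile decomposes the expectation", {
  mod <- test_model(); mach <- test_machine()
  set.seed(910)
  for (k in 1:10) {
    m <- sample(2:5, 1); n <- sample(2:5, 1)
    p <- sequence_pair(random_residues(m), random_residues(n))
    tt <- runif(1, 5, 300)
    ref <- pairwise_alignment(sample(enumerate_alignments(m, n), 1), m, n)
    prof <- expected_distance_profile(p, ref, mod, mach, time = tt)
    expect_length(prof, m + n + 1)
    expect_equal(prof, enum_ead_profile(p, ref, mod, mach, tt),
                 tolerance = 1e-9, ignore_attr = TRUE)
    expect_equal(sum(prof),
                 expected_alignment_distance(p, ref, mod, mach, time = tt)$raw,
                 tolerance = 1e-9)
  }
  # identical sequences at small time, reference on the diagonal: nothing left over
  p <- sequence_pair("ARNDCQ", "ARNDCQ")
  prof <- expected_distance_profile(p, pairwise_alignment(strrep("m", 6), 6, 6),
                                    mod, mach, time = 0.05)
  expect_lt(max(prof), 1e-4)
})

test_that("using the optimal alignment as reference is consistent with its posterior weight", {
  mod <- test_model(); mach <- test_machine()
  p <- sequence_pair("ARNDC", "RNDCW")
  tt <- 120
  oc <- optimal_compare(p, mod, mach, time = tt)
  got <- expected_alignment_distance(p, oc$optimal_alignment, mod, mach, time = tt)
  expect_gte(got$raw, 0)
  # strictly positive here because the posterior is spread over many alignments
  expect_gt(got$raw, 0)
})
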