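test_that("null message length is additive and matches the uniform hand computation", {
  mod <- test_model()
  unif <- rep(1 / 20, 20)
  p11 <- sequence_pair("A", "A")
  expect_equal(null_length(p11, mod, gap_probs = unif),
               2 * (universal_code_bits(1) + log2(20)), tolerance = 1e-12)
  # additivity: the pair null is the sum of two single-sequence nulls
  pa <- sequence_pair("ARNDCQ", "W")
  na_s <- null_length(sequence_pair("ARNDCQ", "ARNDCQ"), mod) / 2
  na_t <- null_length(sequence_pair("W", "W"), mod) / 2
  expect_equal(null_length(pa, mod), na_s + na_t, tolerance = 1e-12)
})

test_that("the optimal alignment equals the exhaustive minimum on small pairs", {
  mod <- test_model(); mach <- test_machine()
  set.seed(101)
  for (k in 1:12) {
    p <- sequence_pair(random_residues(sample(2:4, 1)), random_residues(sample(2:4, 1)))
    tt <- runif(1, 5, 300)
    bits <- enum_alignment_bits(p, mod, mach, tt)
    oc <- optimal_compare(p, mod, mach, time = tt)
    expect_equal(oc$i_optimal_bits, min(bits), tolerance = 1e-9)
    # the returned path re-costs to the reported length, column by column
    expect_equal(alignment_message_bits(p, oc$optimal_alignment, mod, mach, tt),
                 oc$i_optimal_bits, tolerance = 1e-9)
  }
})

test_that("identical sequences align all-match at small times", {
  mod <- test_model(); mach <- test_machine()
  p <- sequence_pair("ARNDCQEGHI", "ARNDCQEGHI")
  for (tt in c(2, 10, 30)) {
    oc <- optimal_compare(p, mod, mach, time = tt)
    expect_identical(oc$optimal_alignment$states, strrep("m", 10))
  }
})

test_that("the forward marginal equals brute-force summation over all alignments", {
  mod <- test_model(); mach <- test_machine()
  # the |S| = |T| = 1 case by explicit hand enumeration of its 3 alignments
  p1 <- sequence_pair("A", "S")
  tt <- 60
  em <- marginalign:::emission_tables(mod, tt)
  mt <- machine_at_time(mach, tt)
  pm <- mt$start[[1]] * em$jm[1, 16] * mt$stop
  pid <- mt$start[[2]] * em$gap[1] * mt$trans[2, 3] * em$gap[16] * mt$stop
  pdi <- mt$start[[3]] * em$gap[16] * mt$trans[3, 2] * em$gap[1] * mt$stop
  mc1 <- marginal_compare(p1, mod, mach, time = tt)
  expect_equal(mc1$i_marginal_bits, -log2(unname(pm + pid + pdi)), tolerance = 1e-9)
  # random small pairs against the enumeration oracle
  set.seed(202)
  for (k in 1:12) {
    p <- sequence_pair(random_residues(sample(1:5, 1)), random_residues(sample(1:5, 1)))
    tt <- runif(1, 3, 400)
    mc <- marginal_compare(p, mod, mach, time = tt, keep_forward = FALSE)
    ref <- enum_marginal_bits(p, mod, mach, tt)
    expect_equal(mc$i_marginal_bits, ref, tolerance = 1e-9)
    # the marginal sums over all alignments, so it can never lose to the best one
    oc <- optimal_compare(p, mod, mach, time = tt)
    expect_lte(mc$i_marginal_bits, oc$i_optimal_bits + 1e-12)
  }
})

test_that("forward matrices combine with the stop cost to the marginal length", {
  mod <- test_model(); mach <- test_machine()
  p <- sequence_pair("ARNDCQEG", "RNDCEGH")
  mc <- marginal_compare(p, mod, mach, time = 120)
  fw <- mc$forward
  i <- p$s_length + 1; j <- p$t_length + 1
  corner <- c(fw$Fm[i, j], fw$Fi[i, j], fw$Fd[i, j])
  combined <- -log2(sum(2^-corner)) + attr(fw, "stop_bits")
  expect_equal(combined, mc$i_marginal_bits, tolerance = 1e-9)
})

test_that("enumerated posteriors normalize and match count_alignments", {
  mod <- test_model(); mach <- test_machine()
  set.seed(303)
  for (k in 1:6) {
    m <- sample(1:4, 1); n <- sample(1:4, 1)
    p <- sequence_pair(random_residues(m), random_residues(n))
    post <- enum_posterior(p, mod, mach, runif(1, 10, 200))
    expect_equal(sum(post), 1, tolerance = 1e-9)
    expect_identical(length(post), as.integer(count_alignments(m, n)))
  }
})

test_that("alignment counts follow the closed form", {
  expect_identical(count_alignments(1, 1), 3)
  expect_identical(count_alignments(2, 2), 13)
  expect_identical(count_alignments(0, 7), 1)
  expect_identical(count_alignments(5, 0), 1)
  expect_identical(count_alignments(5, 5), 1683)
  # closed-form sum over alignment lengths, evaluated independently
  closed <- function(m, n) {
    L <- max(m, n):(m + n)
    sum(factorial(L) / (factorial(L - m) * factorial(L - n) * factorial(m + n - L)))
  }
  for (mn in list(c(3, 5), c(6, 2), c(7, 7)))
    expect_equal(count_alignments(mn[1], mn[2]), closed(mn[1], mn[2]))
  # factorial growth forces exact big-integer arithmetic beyond doubles
  # frozen from an independent exact computation of the closed-form sum
  big <- count_alignments(100, 100)
  expect_type(big, "character")
  expect_identical(nchar(big), 76L)
  expect_identical(substr(big, 1, 20), "20537168308724157702")
  expect_error(count_alignments(-1, 3), "non-negative")
})

test_that("time inference refines a smooth objective and breaks ties to t_min", {
  expect_equal(infer_time(function(t) (t - 100)^2), 100, tolerance = 1e-3)
  expect_equal(infer_time(function(t) (t - 77.3)^2, step = 10), 77.3, tolerance = 1e-3)
  expect_identical(infer_time(function(t) 1), 1)
  expect_error(infer_time(function(t) NaN), "non-finite")
})

test_that("the marginal landscape pins both corners at I_marginal", {
  mod <- test_model(); mach <- test_machine()
  p <- sequence_pair("ARNDCQEGHILK", "RNDAQEGHILKW")
  mc <- marginal_compare(p, mod, mach, time = 90, keep_forward = FALSE)
  L <- landscape(p, mod, mach, 90)
  expect_equal(L[1, 1], mc$i_marginal_bits, tolerance = 1e-6)
  expect_equal(L[nrow(L), ncol(L)], mc$i_marginal_bits, tolerance = 1e-6)
  expect_true(all(is.finite(L)))
  expect_gte(min(L), mc$i_marginal_bits - 1e-6)
  # identical sequences: the low-cost ridge runs along the main diagonal
  q <- sequence_pair("ARNDCQEGHI", "ARNDCQEGHI")
  Lq <- landscape(q, mod, mach, 5)
  for (i in 2:10) expect_identical(which.min(Lq[i, ]), as.integer(i))
})

test_that("significance follows the strict null test, rejecting delta <= 0", {
  expect_true(significance(list(delta_optimal_bits = 246.2))$optimal_significant)
  expect_false(significance(list(delta_marginal_bits = -0.6))$marginal_significant)
  expect_false(significance(list(delta_optimal_bits = 0))$optimal_significant)
  both <- significance(list(delta_optimal_bits = -22.5, delta_marginal_bits = 0.2))
  expect_false(both$optimal_significant)
  expect_true(both$marginal_significant)
  expect_error(significance(list()), "no delta")
})

test_that("pair reversal leaves the marginal unchanged for the reversible default machine", {
  mod <- test_model(); mach <- test_machine()
  set.seed(404)
  for (k in 1:4) {
    s <- random_residues(sample(5:9, 1)); t <- random_residues(sample(5:9, 1))
    rs <- paste(rev(strsplit(s, "")[[1]]), collapse = "")
    rt <- paste(rev(strsplit(t, "")[[1]]), collapse = "")
    tt <- runif(1, 10, 300)
    a <- marginal_compare(sequence_pair(s, t), mod, mach, time = tt, keep_forward = FALSE)
    b <- marginal_compare(sequence_pair(rs, rt), mod, mach, time = tt, keep_forward = FALSE)
    expect_equal(a$i_marginal_bits, b$i_marginal_bits, tolerance = 1e-9)
  }
})
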