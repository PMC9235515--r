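test_that("bundled models parse and satisfy the stochastic-matrix contract", {
  for (nm in c("MMLSUM", "PAM", "BLOSUM", "VTML")) {
    mod <- bundled_model(nm)
    expect_s3_class(mod, "substitution_model")
    expect_true(all(mod$base >= 0))
    expect_lt(max(abs(rowSums(mod$base) - 1)), 1e-12)
    expect_lt(abs(sum(mod$stationary) - 1), 1e-12)
    expect_lt(max(abs(as.vector(mod$stationary %*% mod$base) - mod$stationary)), 1e-8)
  }
  expect_error(bundled_model("WAG"), "unknown model")
})

test_that("matrix_at_time matches integer powers and the semigroup property", {
  mod <- test_model()
  expect_equal(matrix_at_time(mod, 0), diag(20), ignore_attr = TRUE)
  expect_equal(matrix_at_time(mod, 2), mod$base %*% mod$base,
               tolerance = 1e-12, ignore_attr = TRUE)
  # fractional power: M^1.5 squared must reproduce M^3 from repeated squaring
  M3 <- mod$base %*% mod$base %*% mod$base
  M15 <- matrix_at_time(mod, 1.5)
  expect_lt(max(abs(M15 %*% M15 - M3)), 1e-8)
  # semigroup on assorted fractional times
  for (ts in list(c(7.25, 12.5), c(0.5, 99.5), c(150, 150))) {
    lhs <- matrix_at_time(mod, sum(ts))
    rhs <- matrix_at_time(mod, ts[1]) %*% matrix_at_time(mod, ts[2])
    expect_lt(max(abs(lhs - rhs)), 1e-8)
  }
  expect_lt(max(abs(rowSums(matrix_at_time(mod, 333.3)) - 1)), 1e-9)
  expect_error(matrix_at_time(mod, -1), "non-negative")
})

test_that("expected change starts at zero, is monotone, and hits its closed-form limit", {
  mod <- test_model()
  expect_identical(expected_change(mod, 0), 0)
  grid <- expected_change(mod, 1:500)
  expect_true(all(diff(grid) >= 0))
  expect_true(all(grid >= 0 & grid <= 100))
  expect_error(expected_change(mod, -5), "non-negative")
  # uniformizing model: every row equals the stationary distribution, so the
  # infinite-time limit 100 * (1 - sum(pi^2)) is reached at any t > 0
  pi0 <- mod$stationary
  unif <- substitution_model(matrix(pi0, 20, 20, byrow = TRUE), pi0, "uniformizing")
  expect_equal(expected_change(unif, 1000), 100 * (1 - sum(pi0^2)), tolerance = 1e-9)
})

test_that("joint match probabilities normalize and match a brute-force matrix power", {
  mod <- test_model()
  em <- marginalign:::emission_tables(mod, 77.7)
  expect_equal(sum(em$jm[1:20, 1:20]), 1, tolerance = 1e-9)
  # zero-time: off-diagonal joint mass vanishes
  expect_equal(joint_match_probability(mod, 0, "A", "S"), 0, tolerance = 1e-15)
  expect_equal(joint_match_probability(mod, 0, "A", "A"),
               unname(mod$stationary["A"]), tolerance = 1e-12)
  # oracle: repeated matrix multiplication, no eigendecomposition
  Mpow <- diag(20)
  for (k in 1:100) Mpow <- Mpow %*% mod$base
  expect_equal(joint_match_probability(mod, 100, "A", "S"),
               unname(mod$stationary["A"] * Mpow[1, 16]), tolerance = 1e-10)
  expect_error(joint_match_probability(mod, 10, "1", "A"), "unknown residue")
})

test_that("the alignment machine is a proper stopped Markov chain at every time", {
  mach <- test_machine()
  for (t in c(0, 1, 25, 150, 250, 500)) {
    step <- machine_at_time(mach, t)
    expect_true(all(step$trans >= 0 & step$trans <= 1))
    expect_lt(max(abs(rowSums(step$trans) + step$stop - 1)), 1e-12)
    expect_lt(abs(sum(step$start) - 1), 1e-12)
    # detailed balance of the default machine w.r.t. its begin distribution
    flows <- step$start * step$trans
    expect_lt(max(abs(flows - t(flows))), 1e-12)
  }
  # gap pressure grows with divergence
  g <- vapply(c(1, 50, 150, 300, 500),
              function(t) machine_at_time(mach, t)$trans[1, 2], numeric(1))
  expect_true(all(diff(g) > 0))
  expect_error(machine_at_time(mach, -1), "non-negative")
  # a custom transition function is validated against the same contract
  broken <- alignment_machine(transition_fn = function(t)
    list(trans = matrix(0.5, 3, 3), start = c(1, 0, 0), stop = 0.1))
  expect_error(machine_at_time(broken, 10), "sum to 1")
})

test_that("residue policies resolve or reject ambiguity codes", {
  w <- capture_warnings(p <- sequence_pair("ABZ", "AXA"))
  expect_length(w, 2)  # one warning per sequence carrying nonstandard codes
  expect_match(w, "nonstandard", all = TRUE)
  expect_identical(p$s_idx, c(0L, 3L, 6L))   # B -> D, Z -> E
  expect_identical(p$t_idx[2], 20L)          # X -> augmented slot
  expect_error(sequence_pair("ABZ", "AAA", policy = "strict"), "strict")
  expect_error(suppressWarnings(sequence_pair("A1A", "AAA")), "unknown residue")
  expect_error(sequence_pair("", "AAA"), "empty")
})
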