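test_that("pair evolution is deterministic given a seed and validates its inputs", {
  mod <- test_model(); mach <- test_machine()
  a <- evolve_pair(30, 100, mod, mach, seed = 77)
  b <- evolve_pair(30, 100, mod, mach, seed = 77)
  expect_identical(a$pair$s, b$pair$s)
  expect_identical(a$pair$t, b$pair$t)
  expect_identical(a$true_alignment$states, b$true_alignment$states)
  c <- evolve_pair(30, 100, mod, mach, seed = 78)
  expect_false(identical(a$pair$s, c$pair$s))
  # the recorded alignment is valid for the generated pair by construction
  expect_identical(a$true_alignment$s_length, a$pair$s_length)
  expect_identical(a$true_alignment$t_length, a$pair$t_length)
  expect_gte(a$pair$s_length, 30)
  expect_error(evolve_pair(5, 100, mod, mach, seed = 1), "at least 10")
  expect_error(evolve_pair(30, 0, mod, mach, seed = 1), "positive")
  expect_error(evolve_pair(30, 100, mod, mach), "seed")
})

test_that("the identity limit: vanishing time yields identical sequences, all-match", {
  mod <- test_model(); mach <- test_machine()
  sp <- evolve_pair(40, 1e-6, mod, mach, seed = 13)
  expect_identical(sp$pair$s, sp$pair$t)
  expect_identical(sp$true_alignment$states, strrep("m", sp$pair$s_length))
})

test_that("matched-column divergence agrees with the model's expected change", {
  mod <- test_model(); mach <- test_machine()
  tt <- 150
  mism <- 0; tot <- 0
  for (r in 1:25) {
    sp <- evolve_pair(120, tt, mod, mach, seed = 500 + r)
    si <- strsplit(sp$pair$s, "")[[1]]; ti <- strsplit(sp$pair$t, "")[[1]]
    i <- 0; j <- 0
    for (st in strsplit(sp$true_alignment$states, "")[[1]]) {
      if (st == "m") {
        i <- i + 1; j <- j + 1
        tot <- tot + 1
        if (si[i] != ti[j]) mism <- mism + 1
      } else if (st == "i") i <- i + 1 else j <- j + 1
    }
  }
  pexp <- expected_change(mod, tt) / 100
  sigma <- sqrt(pexp * (1 - pexp) / tot)
  expect_lt(abs(mism / tot - pexp), 3 * sigma)
})

test_that("the true alignment's message length tracks the generative entropy rate", {
  mod <- test_model(); mach <- test_machine()
  tt <- 100
  em <- marginalign:::emission_tables(mod, tt)
  mt <- machine_at_time(mach, tt)
  ent <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
  # analytic bits per column: state-occupancy-weighted emission entropy plus
  # the transition entropy of the stopped chain
  phi <- mt$start
  h_emit <- phi[1] * ent(as.vector(em$jm[1:20, 1:20])) +
    (phi[2] + phi[3]) * ent(em$gap[1:20])
  h_trans <- sum(phi * apply(cbind(mt$trans, mt$stop), 1, ent))
  h_col <- h_emit + h_trans
  obs <- vapply(1:15, function(r) {
    sp <- evolve_pair(150, tt, mod, mach, seed = 900 + r)
    alignment_message_bits(sp$pair, sp$true_alignment, mod, mach, tt) /
      nchar(sp$true_alignment$states)
  }, numeric(1))
  expect_lt(abs(mean(obs) - h_col) / h_col, 0.2)
})

test_that("a small recovery experiment re-infers the true divergence", {
  mod <- test_model(); mach <- test_machine()
  rec <- recovery_experiment(50, replicates = 10, length = 100, mod, mach, seed = 60)
  expect_lt(abs(rec$median_time - 50) / 50, 0.15)
  det <- attr(rec, "details")
  expect_identical(nrow(det), 10L)
  expect_true(all(det$delta_marginal > 0))  # daylight pairs compress well
  # identical pairs (vanishing divergence) pin the inferred time at the grid floor
  sp0 <- evolve_pair(40, 1e-6, mod, mach, seed = 3)
  mc0 <- marginal_compare(sp0$pair, mod, mach, keep_forward = FALSE, time_step = 5)
  expect_identical(mc0$time_marginal, 1)
})

test_that("expected distance to the true alignment grows with true divergence", {
  mod <- test_model(); mach <- test_machine()
  meds <- vapply(c(30, 150, 300), function(tt) {
    d <- vapply(1:8, function(r) {
      sp <- evolve_pair(80, tt, mod, mach, seed = 70 + 13 * r)
      expected_alignment_distance(sp$pair, sp$true_alignment, mod, mach,
                                  time = tt)$normalized
    }, numeric(1))
    median(d)
  }, numeric(1))
  expect_true(all(diff(meds) > 0))
})
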