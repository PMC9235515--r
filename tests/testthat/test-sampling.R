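test_that("sampling is reproducible for a fixed seed and leaves the RNG state alone", {
  mod <- test_model(); mach <- test_machine()
  p <- sequence_pair("ARNDC", "RNDCW")
  set.seed(1); before <- rnorm(1)
  s1 <- sample_alignments(p, mod, mach, time = 100, n = 50, seed = 99)
  s2 <- sample_alignments(p, mod, mach, time = 100, n = 50, seed = 99)
  expect_identical(s1$states, s2$states)
  s3 <- sample_alignments(p, mod, mach, time = 100, n = 50, seed = 100)
  expect_false(identical(s1$states, s3$states))
  # every draw is a valid alignment of the pair
  for (st in unique(s1$states))
    expect_no_error(pairwise_alignment(st, 5, 5))
  # the caller's RNG stream is restored
  set.seed(1); expect_identical(rnorm(1), before)
  expect_error(sample_alignments(p, mod, mach, time = 100, n = 10), "seed")
})

test_that("posterior concentration: near-zero time on identical sequences", {
  mod <- test_model(); mach <- test_machine()
  p <- sequence_pair("ARNDCQEG", "ARNDCQEG")
  smp <- sample_alignments(p, mod, mach, time = 0.05, n = 500, seed = 4)
  expect_gt(mean(smp$states == strrep("m", 8)), 0.999)
})

test_that("sampled frequencies follow the exact posterior on enumerable pairs", {
  mod <- test_model(); mach <- test_machine()
  # 1x1: three alignments, frequencies within 3 sigma of the multinomial
  p1 <- sequence_pair("A", "S")
  post1 <- enum_posterior(p1, mod, mach, 100)
  n1 <- 20000
  smp1 <- sample_alignments(p1, mod, mach, time = 100, n = n1, seed = 21)
  counts1 <- table(factor(smp1$states, levels = names(post1)))
  for (a in names(post1)) {
    sigma <- sqrt(n1 * post1[[a]] * (1 - post1[[a]]))
    expect_lt(abs(counts1[[a]] - n1 * post1[[a]]), 3 * sigma + 3)
  }
  # 2x2: chi-square against the exact posterior (tiny-expectation categories
  # pooled, as the chi-square approximation requires)
  p2 <- sequence_pair("AR", "NR")
  post2 <- enum_posterior(p2, mod, mach, 150)
  n2 <- 20000
  smp2 <- sample_alignments(p2, mod, mach, time = 150, n = n2, seed = 22)
  counts2 <- table(factor(smp2$states, levels = names(post2)))
  big <- n2 * post2 >= 5
  obs <- c(counts2[big], pooled = sum(counts2[!big]))
  pr <- c(post2[big], pooled = sum(post2[!big]))
  keep <- pr > 0
  chi <- suppressWarnings(chisq.test(obs[keep], p = pr[keep] / sum(pr[keep])))
  expect_gt(chi$p.value, 0.001)
})

test_that("the empirical expected distance agrees with the exact dynamic program", {
  mod <- test_model(); mach <- test_machine()
  set.seed(31)
  for (k in 1:5) {
    m <- sample(4:7, 1); n <- sample(4:7, 1)
    p <- sequence_pair(random_residues(m), random_residues(n))
    tt <- runif(1, 30, 250)
    ref <- pairwise_alignment(sample(enumerate_alignments(m, n), 1), m, n)
    exact <- expected_alignment_distance(p, ref, mod, mach, time = tt)$normalized
    emp <- empirical_expected_distance(p, ref, mod, mach, time = tt,
                                       n = 1000, seed = 40 + k)
    expect_lt(abs(emp$mean - exact), 3 * emp$se + 1e-9)
  }
  # a reference carrying all posterior mass gives zero mean and zero SE
  q <- sequence_pair("ARNDCQEGHI", "ARNDCQEGHI")
  emp0 <- empirical_expected_distance(q, pairwise_alignment(strrep("m", 10), 10, 10),
                                      mod, mach, time = 0.05, n = 200, seed = 9)
  expect_identical(emp0$mean, 0)
  expect_identical(emp0$se, 0)
})

test_that("Monte-Carlo error shrinks as one over the square root of the sample size", {
  mod <- test_model(); mach <- test_machine()
  p <- sequence_pair("ARNDCQEG", "RNDAQEGW")
  tt <- 150
  ref <- pairwise_alignment("mmmmmmmid", 8, 8)
  exact <- expected_alignment_distance(p, ref, mod, mach, time = tt)$normalized
  sizes <- c(100, 1000, 10000)
  med_err <- vapply(sizes, function(n) {
    errs <- vapply(1:8, function(s)
      abs(empirical_expected_distance(p, ref, mod, mach, time = tt, n = n,
                                      seed = 1000 * s + n)$mean - exact),
      numeric(1))
    median(errs)
  }, numeric(1))
  slope <- coef(lm(log(med_err) ~ log(sizes)))[2]
  expect_lt(abs(slope + 0.5), 0.15)
})
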