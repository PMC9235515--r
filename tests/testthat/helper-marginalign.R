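# Shared fixtures and independent oracles for the test suite. The oracles
# work by explicit enumeration / direct probability products and never touch
# the C++ dynamic programs they are held against.

test_model <- local({
  cached <- NULL
  function() {
    if (is.null(cached)) cached <<- bundled_model("MMLSUM")
    cached
  }
})

test_machine <- local({
  cached <- NULL
  function() {
    if (is.null(cached)) cached <<- alignment_machine()
    cached
  }
})

random_residues <- function(n, alphabet = c("A", "R", "N", "D", "C", "Q", "E", "G")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# enumeration-based joint message lengths of every alignment of a pair
enum_alignment_bits <- function(pair, model, machine, time) {
  alns <- enumerate_alignments(pair$s_length, pair$t_length)
  bits <- vapply(alns, function(a)
    alignment_message_bits(pair, pairwise_alignment(a, pair$s_length, pair$t_length),
                           model, machine, time),
    numeric(1))
  names(bits) <- alns
  bits
}

# marginal message length by brute-force summation over all alignments
enum_marginal_bits <- function(pair, model, machine, time) {
  bits <- enum_alignment_bits(pair, model, machine, time)
  mn <- min(bits)
  mn - log2(sum(2^-(bits - mn)))
}

# exact posterior distribution over all alignments
enum_posterior <- function(pair, model, machine, time) {
  bits <- enum_alignment_bits(pair, model, machine, time)
  w <- 2^-(bits - min(bits))
  w / sum(w)
}

# posterior-weighted expected distance to a reference, by enumeration
enum_ead <- function(pair, a_ref, model, machine, time) {
  post <- enum_posterior(pair, model, machine, time)
  d <- vapply(names(post), function(a)
    alignment_distance(pairwise_alignment(a, pair$s_length, pair$t_length), a_ref),
    numeric(1))
  list(raw = sum(post * d), distances = d, posterior = post)
}

# per-skew-diagonal expected widths, by enumeration
enum_ead_profile <- function(pair, a_ref, model, machine, time) {
  post <- enum_posterior(pair, model, machine, time)
  ref_profile <- diagonal_profile(a_ref)
  E <- numeric(pair$s_length + pair$t_length + 1)
  for (a in names(post)) {
    pa <- diagonal_profile(pairwise_alignment(a, pair$s_length, pair$t_length))
    E <- E + post[[a]] * abs(pa - ref_profile)
  }
  E
}

# independent path walker: profile from the explicit list of visited lattice
# points (used to cross-check diagonal_profile's two-crossing match rule)
walk_profile <- function(states, m, n) {
  i <- 0L; j <- 0L
  pi_k <- rep(NA_integer_, m + n + 1L)
  pi_k[1] <- 0L
  for (s in strsplit(states, "")[[1]]) {
    if (s == "m") {
      # the diagonal move crosses skew diagonals i+j+1 and i+j+2 (1-based)
      pi_k[i + j + 2L] <- (j + 1L) - (i + 1L)
      i <- i + 1L; j <- j + 1L
      pi_k[i + j + 1L] <- j - i
    } else if (s == "i") {
      i <- i + 1L
      pi_k[i + j + 1L] <- j - i
    } else {
      j <- j + 1L
      pi_k[i + j + 1L] <- j - i
    }
  }
  pi_k
}
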