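#' Expected distance of all alignments to a reference alignment
#'
#' The central statistic of the package: the exact mathematical expectation of
#' the inter-alignment distance between the sequence alignments of a pair and
#' a fixed reference alignment (typically derived from structure),
#' \deqn{E[distance(A, A_{ref})] = \sum_A Pr(A | \langle S,T\rangle) \,
#'       distance(A, A_{ref}),}
#' where the posterior weights are the alignment joint probabilities
#' normalized by the marginal. Despite the factorially large alignment space
#' the expectation is computed exactly in `O(|S||T|)` time and space by a
#' three-matrix dynamic program that propagates, per ending state, the
#' distance mass accumulated against the reference path's skew-diagonal
#' profile (a match move crossing two skew diagonals contributes two width
#' terms, insert/delete moves one).
#'
#' @param pair a `sequence_pair`.
#' @param a_ref a `pairwise_alignment` of the same pair (the reference).
#' @param model a `substitution_model`.
#' @param machine an `alignment_machine`.
#' @param time Markov time; if `NULL` (default), `time_marginal` is inferred
#'   with [marginal_compare()] first.
#' @param gap_probs optional override of the 20-nomial gap emission.
#' @return list with `raw` (expected distance in width units), `normalized`
#'   (`raw / (|S| + |T|)`, the length-calibrated value reported by the
#'   package) and `time` (the Markov time used).
#' @export
#' @examples
#' mach <- alignment_machine()
#' mod <- bundled_model("MMLSUM")
#' p <- sequence_pair("ARNDAY", "ARNDAY")
#' ref <- pairwise_alignment("mmmmmm", 6, 6)
#' expected_alignment_distance(p, ref, mod, mach, time = 5)
expected_alignment_distance <- function(pair, a_ref, model, machine,
                                        time = NULL, gap_probs = NULL) {
  stopifnot(inherits(pair, "sequence_pair"), inherits(a_ref, "pairwise_alignment"))
  if (a_ref$s_length != pair$s_length || a_ref$t_length != pair$t_length)
    stop("reference alignment is inconsistent with the pair's sequence lengths")
  if (is.null(time))
    time <- marginal_compare(pair, model, machine, keep_forward = FALSE,
                             gap_probs = gap_probs)$time_marginal
  inp <- dp_inputs(pair, model, machine, time, gap_probs)
  inp$piref <- diagonal_profile(a_ref)
  raw <- do.call(ead_cpp, inp)$expectation
  list(raw = raw,
       normalized = normalized_distance(raw, pair$s_length, pair$t_length),
       time = time)
}

#' Per-skew-diagonal decomposition of the expected distance
#'
#' Splits the expected inter-alignment distance by skew diagonal: element
#' `k + 1` is the posterior-expected width between the sequence alignments
#' and the reference at skew diagonal `k`. The vector sums to the raw
#' expectation of [expected_alignment_distance()] and localizes where the
#' sequence evidence disagrees with the reference.
#'
#' @inheritParams expected_alignment_distance
#' @return numeric vector of length `|S| + |T| + 1`.
#' @export
expected_distance_profile <- function(pair, a_ref, model, machine,
                                      time = NULL, gap_probs = NULL) {
  stopifnot(inherits(pair, "sequence_pair"), inherits(a_ref, "pairwise_alignment"))
  if (a_ref$s_length != pair$s_length || a_ref$t_length != pair$t_length)
    stop("reference alignment is inconsistent with the pair's sequence lengths")
  if (is.null(time))
    time <- marginal_compare(pair, model, machine, keep_forward = FALSE,
                             gap_probs = gap_probs)$time_marginal
  inp <- dp_inputs(pair, model, machine, time, gap_probs)
  fwd <- do.call(fwd_log_cpp, inp)
  bwd <- do.call(bwd_log_cpp, inp[c("sidx", "tidx", "jm", "gs", "gt", "trans", "rho")])
  m <- pair$s_length; n <- pair$t_length
  log_marg <- -fwd$bits * log(2)
  post <- function(L, B) {
    p <- exp(L + B - log_marg)
    p[1, 1] <- 0  # cell (0,0) is the begin pseudo-state; its width is 0 anyway
    p
  }
  Pm <- post(fwd$Lm, bwd$Bm)
  Pi_ <- post(fwd$Li, bwd$Bi)
  Pd <- post(fwd$Ld, bwd$Bd)
  piref <- diagonal_profile(a_ref)
  K <- outer(0:m, 0:n, "+")
  C <- outer(0:m, 0:n, function(i, j) j - i)
  delta_here <- abs(C - matrix(piref[K + 1], m + 1, n + 1))
  E <- numeric(m + n + 1)
  cellsum <- rowsum(as.vector((Pm + Pi_ + Pd) * delta_here), as.vector(K))
  E[as.integer(rownames(cellsum)) + 1] <- cellsum
  # the extra width of the match move's first skew crossing (index i+j-1)
  ok <- K >= 1
  delta_prev <- matrix(0, m + 1, n + 1)
  delta_prev[ok] <- abs(C[ok] - piref[K[ok]])
  extra <- rowsum(as.vector(Pm * delta_prev)[ok], as.vector(K - 1)[ok])
  idx <- as.integer(rownames(extra)) + 1
  E[idx] <- E[idx] + extra
  E
}
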