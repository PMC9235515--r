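#' Sample alignments from the posterior by stochastic traceback
#'
#' Draws alignments of a pair with probability exactly equal to their
#' posterior `Pr(A | <S,T>)`, by backward stochastic traceback over the
#' per-state forward matrices: starting from the sink, each predecessor state
#' is drawn proportional to its forward mass times the connecting transition
#' probability. Reproducible for a fixed seed.
#'
#' @param pair a `sequence_pair`.
#' @param model a `substitution_model`.
#' @param machine an `alignment_machine`.
#' @param time Markov time of the marginal matrices; if `NULL`,
#'   `time_marginal` is inferred first.
#' @param n number of alignments to draw.
#' @param seed mandatory RNG seed (no global state is consumed).
#' @param gap_probs optional override of the 20-nomial gap emission.
#' @return object of class `alignment_sample`: list with `states` (character
#'   vector of three-state strings), `s_length`, `t_length`, `time`, `seed`.
#' @export
sample_alignments <- function(pair, model, machine, time = NULL, n = 1000,
                              seed, gap_probs = NULL) {
  stopifnot(inherits(pair, "sequence_pair"), n >= 1)
  if (missing(seed)) stop("a seed is required for reproducible sampling")
  if (is.null(time))
    time <- marginal_compare(pair, model, machine, keep_forward = FALSE,
                             gap_probs = gap_probs)$time_marginal
  inp <- dp_inputs(pair, model, machine, time, gap_probs)
  fwd <- do.call(fwd_scaled_cpp, c(inp, list(keep = TRUE)))
  if (!is.finite(fwd$bits)) stop("degenerate marginal matrices; cannot sample")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  states <- sample_paths_cpp(as.integer(n), fwd$Fm, fwd$Fi, fwd$Fd,
                             inp$trans, inp$phi)
  structure(list(states = as.character(states), s_length = pair$s_length,
                 t_length = pair$t_length, time = time, seed = seed),
            class = "alignment_sample")
}

#' @export
print.alignment_sample <- function(x, ...) {
  cat(sprintf("alignment_sample: %d draws for |S|=%d, |T|=%d at time %.2f (seed %s)\n",
              length(x$states), x$s_length, x$t_length, x$time, format(x$seed)))
  invisible(x)
}

#' Empirical (sampling) estimate of the expected distance
#'
#' The Monte-Carlo counterpart of [expected_alignment_distance()]: draws `n`
#' alignments from the posterior and averages their normalized distance to
#' the reference alignment. Used to validate the exact dynamic program.
#'
#' @inheritParams sample_alignments
#' @param a_ref the reference `pairwise_alignment`.
#' @return list with `mean`, `se` (standard error), `n`, `time`, `seed` and
#'   the per-sample normalized `distances`.
#' @export
empirical_expected_distance <- function(pair, a_ref, model, machine,
                                        time = NULL, n = 1000, seed,
                                        gap_probs = NULL) {
  stopifnot(inherits(a_ref, "pairwise_alignment"))
  if (a_ref$s_length != pair$s_length || a_ref$t_length != pair$t_length)
    stop("reference alignment is inconsistent with the pair's sequence lengths")
  smp <- sample_alignments(pair, model, machine, time, n, seed, gap_probs)
  ref_profile <- diagonal_profile(a_ref)
  tot <- pair$s_length + pair$t_length
  d <- vapply(smp$states, function(st) {
    a <- pairwise_alignment(st, pair$s_length, pair$t_length)
    sum(abs(diagonal_profile(a) - ref_profile)) / tot
  }, numeric(1), USE.NAMES = FALSE)
  list(mean = mean(d), se = if (n > 1) sd(d) / sqrt(n) else 0,
       n = n, time = smp$time, seed = seed, distances = d)
}
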