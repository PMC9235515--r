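#' Three-state alignment machine
#'
#' The time-parameterized finite-state machine over the states match (m),
#' insert (i, consumes S) and delete (d, consumes T) that generates alignment
#' state strings. The default machine is a smooth, reversible stand-in for the
#' published machines of this model family: the per-move gap probability
#' `g(t) = g_max * (1 - exp(-t/tau)) / (1 + exp(-(t - t0)/s))` vanishes at
#' `t = 0` and grows logistically with Markov time, the machine satisfies
#' detailed balance with respect to its stationary state distribution
#' `phi(t) = (1 - 2*r*g, r*g, r*g)`, and `phi(t)` is also the begin
#' distribution, which makes every alignment path's probability invariant
#' under reversal of the sequence pair. A per-step stop probability `rho`
#' terminates (and so self-delimits) the alignment message. All downstream
#' code depends only on the contract of [machine_at_time()]; a custom
#' `transition_fn` may replace the default entirely.
#'
#' @param gap_max asymptotic per-move gap-open probability (default 0.08).
#' @param gap_tau time constant of the low-divergence rise (default 50).
#' @param gap_mid,gap_scale center and width of the logistic growth in `t`
#'   (defaults 200 and 100).
#' @param gap_occupancy ratio `r` of gap-state to gap-open probability in the
#'   stationary state distribution (default 2.5); controls gap length.
#' @param cross_gap fraction of gap-state flow going to the opposite gap state
#'   (default 0.1).
#' @param stop_prob per-step stop probability `rho` (default 0.002, i.e. a
#'   mean alignment length of 500 columns).
#' @param transition_fn optional replacement: a function of `t` returning a
#'   list with elements `trans` (3x3 matrix, `trans[p, q] = Pr(q | p)`, rows
#'   summing to `1 - stop`), `start` (length-3 begin distribution) and `stop`.
#' @return an object of class `alignment_machine`.
#' @export
#' @examples
#' mach <- alignment_machine()
#' machine_at_time(mach, 150)$trans
alignment_machine <- function(gap_max = 0.08, gap_tau = 50, gap_mid = 200,
                              gap_scale = 100, gap_occupancy = 2.5,
                              cross_gap = 0.1, stop_prob = 0.002,
                              transition_fn = NULL) {
  stopifnot(gap_max > 0, gap_max < 1 / (2 * gap_occupancy),
            stop_prob > 0, stop_prob < 1, cross_gap >= 0)
  structure(list(gap_max = gap_max, gap_tau = gap_tau, gap_mid = gap_mid,
                 gap_scale = gap_scale, gap_occupancy = gap_occupancy,
                 cross_gap = cross_gap, stop_prob = stop_prob,
                 transition_fn = transition_fn),
            class = "alignment_machine")
}

#' Machine transition probabilities at a Markov time
#'
#' Evaluates the three-state machine at time `t` and validates the result:
#' every outgoing distribution (including the stop mass) sums to 1.
#'
#' @param machine an `alignment_machine`.
#' @param t non-negative Markov time.
#' @return a list with `trans` (3x3 matrix, `trans[p, q] = Pr(q | p)` over
#'   states in the order m, i, d), `start` (begin distribution) and `stop`
#'   (per-step stop probability).
#' @export
machine_at_time <- function(machine, t) {
  stopifnot(inherits(machine, "alignment_machine"))
  if (length(t) != 1 || !is.finite(t) || t < 0)
    stop("Markov time t must be a single non-negative number")
  if (!is.null(machine$transition_fn)) {
    out <- machine$transition_fn(t)
  } else {
    rho <- machine$stop_prob
    r <- machine$gap_occupancy
    chi <- machine$cross_gap
    g <- machine$gap_max * (1 - exp(-t / machine$gap_tau)) /
      (1 + exp(-(t - machine$gap_mid) / machine$gap_scale))
    open_back <- (1 - 2 * r * g) / r          # Pr(m | i) = Pr(m | d)
    gap_stay <- (1 - rho) - (1 + chi) * open_back
    if (gap_stay < 0)
      stop("machine parameters give a negative gap self-transition")
    trans <- rbind(m = c(1 - rho - 2 * g, g, g),
                   i = c(open_back, gap_stay, chi * open_back),
                   d = c(open_back, chi * open_back, gap_stay))
    colnames(trans) <- c("m", "i", "d")
    out <- list(trans = trans,
                start = c(m = 1 - 2 * r * g, i = r * g, d = r * g),
                stop = rho)
  }
  validate_machine_step(out)
  out
}

validate_machine_step <- function(step) {
  tr <- step$trans
  if (!is.matrix(tr) || any(dim(tr) != 3))
    stop("machine transition matrix must be 3x3")
  if (any(tr < 0) || any(tr > 1) || any(step$start < 0) ||
      step$stop < 0 || step$stop > 1)
    stop("machine probabilities must lie in [0, 1]")
  if (any(abs(rowSums(tr) + step$stop - 1) > 1e-12))
    stop("each machine state's outgoing distribution (with stop) must sum to 1")
  if (abs(sum(step$start) - 1) > 1e-12)
    stop("machine begin distribution must sum to 1")
  invisible(step)
}

#' @export
print.alignment_machine <- function(x, ...) {
  cat("alignment_machine (three-state m/i/d, time-parameterized)\n")
  if (is.null(x$transition_fn)) {
    cat(sprintf("  gap_max=%.3g tau=%.3g mid=%.3g scale=%.3g occupancy=%.3g cross=%.3g stop=%.3g\n",
                x$gap_max, x$gap_tau, x$gap_mid, x$gap_scale,
                x$gap_occupancy, x$cross_gap, x$stop_prob))
  } else cat("  custom transition function\n")
  invisible(x)
}
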