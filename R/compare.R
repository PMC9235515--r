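#' Construct a validated sequence pair
#'
#' @param s,t residue strings (will be uppercased).
#' @param id optional pair identifier used in result tables.
#' @param policy `"lenient"` resolves ambiguity codes (B, Z, U, O, J mapped to
#'   a standard residue; X encoded by its stationary expectation) with a
#'   warning; `"strict"` rejects them.
#' @return an object of class `sequence_pair` with the raw strings, their
#'   encoded indices and lengths.
#' @export
sequence_pair <- function(s, t, id = NULL, policy = c("lenient", "strict")) {
  policy <- match.arg(policy)
  sidx <- encode_residues(s, policy, "sequence S")
  tidx <- encode_residues(t, policy, "sequence T")
  structure(list(s = toupper(s), t = toupper(t),
                 s_idx = sidx, t_idx = tidx,
                 s_length = length(sidx), t_length = length(tidx),
                 id = if (is.null(id)) "pair" else id, policy = policy),
            class = "sequence_pair")
}

#' @export
print.sequence_pair <- function(x, ...) {
  cat(sprintf("sequence_pair '%s': |S|=%d, |T|=%d (%s policy)\n",
              x$id, x$s_length, x$t_length, x$policy))
  invisible(x)
}

# Assemble all per-time inputs of the dynamic programs.
dp_inputs <- function(pair, model, machine, t, gap_probs = NULL) {
  em <- emission_tables(model, t, gap_probs)
  mt <- machine_at_time(machine, t)
  list(sidx = pair$s_idx, tidx = pair$t_idx, jm = em$jm, gs = em$gap,
       gt = em$gap, trans = unname(mt$trans), phi = unname(mt$start),
       rho = mt$stop)
}

#' Null-model message length of a pair
#'
#' The lossless encoding length of both sequences without any alignment
#' hypothesis: for each sequence, a universal integer code for its length
#' plus the 20-nomial code for its residues (by default the model's
#' stationary distribution). Additive over the two sequences.
#'
#' @param pair a `sequence_pair`.
#' @param model a `substitution_model` supplying the 20-nomial.
#' @param gap_probs optional override of the 20-nomial residue distribution.
#' @return message length in bits.
#' @export
null_length <- function(pair, model, gap_probs = NULL) {
  stopifnot(inherits(pair, "sequence_pair"))
  em <- emission_tables(model, 1, gap_probs)  # gap vector is time-independent
  one <- function(idx) universal_code_bits(length(idx)) - sum(log2(em$gap[idx + 1L]))
  one(pair$s_idx) + one(pair$t_idx)
}

#' Infer a Markov time by grid scan and golden-section refinement
#'
#' Minimizes `objective(t)` over `[lower, upper]`: a deterministic scan over
#' the grid `seq(lower, upper, by = step)` (ties broken toward the smallest
#' `t`) followed by golden-section refinement inside the one-step bracket
#' around the grid minimum. If refinement does not strictly improve on the
#' grid value, the grid minimizer is returned unchanged.
#'
#' @param objective function of a single time value, finite somewhere on the
#'   interval.
#' @param lower,upper search bounds (defaults 1 and 500).
#' @param step grid spacing (default 1).
#' @param refine if `FALSE`, return the grid minimizer without refinement.
#' @return the inferred time.
#' @export
infer_time <- function(objective, lower = 1, upper = 500, step = 1, refine = TRUE) {
  grid <- seq(lower, upper, by = step)
  vals <- vapply(grid, objective, numeric(1))
  if (all(!is.finite(vals))) stop("objective is non-finite over the whole time grid")
  vals[!is.finite(vals)] <- Inf
  best <- which.min(vals)  # first minimum: ties resolve toward t_min
  t_best <- grid[best]; v_best <- vals[best]
  if (!refine) return(t_best)
  lo <- max(lower, t_best - step); hi <- min(upper, t_best + step)
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
  f1 <- objective(x1); f2 <- objective(x2)
  for (k in 1:40) {
    if (b - a < 1e-6) break
    if (f1 <= f2) { b <- x2; x2 <- x1; f2 <- f1; x1 <- b - gr * (b - a); f1 <- objective(x1) }
    else { a <- x1; x1 <- x2; f1 <- f2; x2 <- a + gr * (b - a); f2 <- objective(x2) }
  }
  t_ref <- if (f1 <= f2) x1 else x2
  v_ref <- min(f1, f2)
  if (is.finite(v_ref) && v_ref < v_best) t_ref else t_best
}

#' Marginalized sequence comparison
#'
#' Computes the marginal message length
#' `I_marginal = -log2 sum_A Pr(A, <S,T>)`, summing the joint probabilities of
#' all alignments by the forward algorithm, and (unless `time` is given)
#' infers the unbiased divergence parameter `time_marginal` by minimizing
#' `I_marginal(t)` over the time grid.
#'
#' @param pair a `sequence_pair`.
#' @param model a `substitution_model`.
#' @param machine an `alignment_machine`.
#' @param time fixed Markov time; if `NULL` (default) the time is inferred.
#' @param time_range,time_step search range and grid spacing for time
#'   inference (defaults `[1, 500]`, step 1).
#' @param gap_probs optional override of the 20-nomial gap emission.
#' @param keep_forward if `TRUE` (default) the three per-state forward
#'   matrices (negative log2 of the summed joint probability of all prefix
#'   alignments ending at each cell in each state) are returned.
#' @return an object of class `mml_comparison` with elements
#'   `i_marginal_bits`, `null_bits`, `delta_marginal_bits`, `time_marginal`
#'   and (optionally) `forward` (list of matrices `Fm`, `Fi`, `Fd` in bits,
#'   with attribute `stop_bits`).
#' @export
marginal_compare <- function(pair, model, machine, time = NULL,
                             time_range = c(1, 500), time_step = 1,
                             gap_probs = NULL, keep_forward = TRUE) {
  stopifnot(inherits(pair, "sequence_pair"))
  objective <- function(t)
    do.call(fwd_bits_cpp, dp_inputs(pair, model, machine, t, gap_probs))
  t_star <- if (is.null(time)) {
    infer_time(objective, time_range[1], time_range[2], time_step)
  } else {
    if (time < 0) stop("Markov time must be non-negative")
    time
  }
  nb <- null_length(pair, model, gap_probs)
  out <- list(pair_id = pair$id, s_length = pair$s_length, t_length = pair$t_length,
              null_bits = nb, time_marginal = t_star)
  if (keep_forward) {
    fl <- do.call(fwd_log_cpp, c(dp_inputs(pair, model, machine, t_star, gap_probs)))
    out$i_marginal_bits <- fl$bits
    conv <- function(L) -L / log(2)
    fwd <- list(Fm = conv(fl$Lm), Fi = conv(fl$Li), Fd = conv(fl$Ld))
    attr(fwd, "stop_bits") <- -log2(machine_at_time(machine, t_star)$stop)
    attr(fwd, "time") <- t_star
    out$forward <- fwd
  } else {
    out$i_marginal_bits <- objective(t_star)
  }
  out$delta_marginal_bits <- nb - out$i_marginal_bits
  structure(out, class = "mml_comparison", mode = "marginal")
}

#' Optimal (minimum message length) sequence comparison
#'
#' Finds the alignment minimizing the two-part message length
#' `I(A, <S,T>) = I(A) + I(<S,T> | A)` by Viterbi dynamic programming, and
#' (unless `time` is given) the biased divergence parameter `time_optimal`
#' minimizing that length over the time grid. Ties in the traceback prefer
#' match over delete over insert, so the returned alignment is deterministic.
#'
#' @inheritParams marginal_compare
#' @return an `mml_comparison` with `i_optimal_bits`, `null_bits`,
#'   `delta_optimal_bits`, `time_optimal` and `optimal_alignment`
#'   (a [pairwise_alignment()]).
#' @export
optimal_compare <- function(pair, model, machine, time = NULL,
                            time_range = c(1, 500), time_step = 1,
                            gap_probs = NULL) {
  stopifnot(inherits(pair, "sequence_pair"))
  objective <- function(t)
    do.call(viterbi_cpp, dp_inputs(pair, model, machine, t, gap_probs))$bits
  t_star <- if (is.null(time)) {
    infer_time(objective, time_range[1], time_range[2], time_step)
  } else {
    if (time < 0) stop("Markov time must be non-negative")
    time
  }
  vit <- do.call(viterbi_cpp, dp_inputs(pair, model, machine, t_star, gap_probs))
  nb <- null_length(pair, model, gap_probs)
  structure(list(pair_id = pair$id, s_length = pair$s_length,
                 t_length = pair$t_length, null_bits = nb,
                 i_optimal_bits = vit$bits,
                 delta_optimal_bits = nb - vit$bits,
                 time_optimal = t_star,
                 optimal_alignment = pairwise_alignment(vit$states,
                                                        pair$s_length,
                                                        pair$t_length)),
            class = "mml_comparison", mode = "optimal")
}

#' Full MML comparison of a sequence pair
#'
#' Runs both the optimal and the marginal comparison and merges the results.
#'
#' @inheritParams marginal_compare
#' @return an `mml_comparison` with all optimal and marginal fields plus the
#'   significance flags of [significance()].
#' @export
mml_compare <- function(pair, model, machine, time = NULL,
                        time_range = c(1, 500), time_step = 1,
                        gap_probs = NULL, keep_forward = TRUE) {
  mar <- marginal_compare(pair, model, machine, time, time_range, time_step,
                          gap_probs, keep_forward)
  opt <- optimal_compare(pair, model, machine, time, time_range, time_step,
                         gap_probs)
  out <- c(unclass(mar),
           opt[c("i_optimal_bits", "delta_optimal_bits", "time_optimal",
                 "optimal_alignment")])
  out <- structure(out, class = "mml_comparison", mode = "full")
  out[c("optimal_significant", "marginal_significant")] <- significance(out)
  out
}

#' Null-model significance of a comparison
#'
#' The MML null test: a hypothesis is accepted only if it compresses the data
#' relative to the null message, i.e. if its `delta` is strictly positive
#' (`NULL - I <= 0` rejects).
#'
#' @param result an `mml_comparison` (or any list with the delta fields).
#' @return list with logical `optimal_significant` and/or
#'   `marginal_significant` flags for the fields present.
#' @export
significance <- function(result) {
  out <- list()
  if (!is.null(result$delta_optimal_bits))
    out$optimal_significant <- result$delta_optimal_bits > 0
  if (!is.null(result$delta_marginal_bits))
    out$marginal_significant <- result$delta_marginal_bits > 0
  if (!length(out)) stop("result carries no delta statistics")
  out
}

#' @export
print.mml_comparison <- function(x, ...) {
  cat(sprintf("mml_comparison '%s' (|S|=%d, |T|=%d)\n",
              x$pair_id, x$s_length, x$t_length))
  cat(sprintf("  null      : %8.1f bits\n", x$null_bits))
  if (!is.null(x$i_optimal_bits))
    cat(sprintf("  optimal   : %8.1f bits (delta %+.1f, time %.1f)\n",
                x$i_optimal_bits, x$delta_optimal_bits, x$time_optimal))
  if (!is.null(x$i_marginal_bits))
    cat(sprintf("  marginal  : %8.1f bits (delta %+.1f, time %.1f)\n",
                x$i_marginal_bits, x$delta_marginal_bits, x$time_marginal))
  invisible(x)
}

#' Marginal probability landscape of a pair
#'
#' For every cell `(i, j)` the landscape stores the negative log2 of the
#' product of the marginal probability that the prefixes `S[1..i]`, `T[1..j]`
#' are related and the marginal probability that the suffixes are related.
#' The suffix marginals come from a forward pass over the reversed pair; the
#' empty prefix and the empty suffix have probability 1, so the cells
#' `(0, 0)` and `(|S|, |T|)` both equal `I_marginal` (exactly, for the
#' reversible default machine). Low values trace the high-probability
#' alignment corridor.
#'
#' @inheritParams marginal_compare
#' @param time Markov time at which to evaluate (required; typically
#'   `time_marginal` from [marginal_compare()]).
#' @return a matrix of class `mml_landscape` with attributes `i_marginal_bits`
#'   and `time`.
#' @export
landscape <- function(pair, model, machine, time, gap_probs = NULL) {
  stopifnot(inherits(pair, "sequence_pair"))
  inp <- dp_inputs(pair, model, machine, time, gap_probs)
  fwd <- do.call(fwd_log_cpp, inp)
  rev_inp <- inp
  rev_inp$sidx <- rev(inp$sidx)
  rev_inp$tidx <- rev(inp$tidx)
  bwd <- do.call(fwd_log_cpp, rev_inp)
  m <- pair$s_length; n <- pair$t_length
  cellbits <- function(fl) {  # -log2 marginal of prefix (i, j); empty prefix = 0
    mx <- pmax(fl$Lm, fl$Li, fl$Ld)
    lse <- ifelse(is.finite(mx),
                  mx + log(exp(fl$Lm - mx) + exp(fl$Li - mx) + exp(fl$Ld - mx)),
                  -Inf)
    b <- -(lse + log(inp$rho)) / log(2)
    b[1, 1] <- 0
    b
  }
  pre <- cellbits(fwd)
  suf <- cellbits(bwd)[m + 1 - (0:m), n + 1 - (0:n), drop = FALSE]
  L <- pre + suf
  structure(L, class = c("mml_landscape", "matrix"),
            i_marginal_bits = fwd$bits, time = time)
}

#' Export a landscape as a dense text matrix
#'
#' @param x an `mml_landscape`.
#' @param path output file.
#' @export
write_landscape <- function(x, path) {
  stopifnot(inherits(x, "mml_landscape"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# marginal probability landscape: %d x %d, I_marginal=%.6f bits, time=%.6f",
                     nrow(x), ncol(x), attr(x, "i_marginal_bits"), attr(x, "time")), con)
  write.table(format(unclass(x), digits = 10, trim = TRUE), con,
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
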