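# Brute-force enumeration utilities. These are the independent oracles the
# test suite holds the dynamic programs against: they never share code with
# the C++ recurrences.

#' Enumerate every alignment of two sequence lengths
#'
#' Generates all three-state strings for a pair of lengths `(m, n)` by direct
#' recursion over the last move. Practical only for tiny instances (the count
#' grows factorially; see [count_alignments()]).
#'
#' @param m,n non-negative sequence lengths.
#' @return character vector of state strings (one per alignment).
#' @export
enumerate_alignments <- function(m, n) {
  if (m < 0 || n < 0) stop("lengths must be non-negative")
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (i == 0 && j == 0) return("")
    key <- paste(i, j)
    got <- memo[[key]]
    if (!is.null(got)) return(got)
    out <- character(0)
    if (i > 0 && j > 0) out <- c(out, paste0(rec(i - 1, j - 1), "m"))
    if (i > 0) out <- c(out, paste0(rec(i - 1, j), "i"))
    if (j > 0) out <- c(out, paste0(rec(i, j - 1), "d"))
    memo[[key]] <- out
    out
  }
  rec(m, n)
}

#' Two-part message length of one alignment, computed directly
#'
#' Evaluates `I(A, <S,T>) = -log2 Pr(A, <S,T>)` for a single alignment by
#' walking its state string and multiplying the begin, transition, stop and
#' emission probabilities column by column — no dynamic programming involved.
#' This is the reference computation against which the Viterbi and forward
#' passes are validated, and it doubles as the independent re-costing of a
#' returned optimal alignment.
#'
#' @param pair a `sequence_pair`.
#' @param alignment a `pairwise_alignment` of the pair.
#' @param model a `substitution_model`.
#' @param machine an `alignment_machine`.
#' @param time Markov time.
#' @param gap_probs optional override of the 20-nomial gap emission.
#' @return message length in bits.
#' @export
alignment_message_bits <- function(pair, alignment, model, machine, time,
                                   gap_probs = NULL) {
  stopifnot(inherits(pair, "sequence_pair"),
            inherits(alignment, "pairwise_alignment"))
  if (alignment$s_length != pair$s_length || alignment$t_length != pair$t_length)
    stop("alignment is inconsistent with the pair's sequence lengths")
  em <- emission_tables(model, time, gap_probs)
  mt <- machine_at_time(machine, time)
  states <- strsplit(alignment$states, "", fixed = TRUE)[[1]]
  qidx <- match(states, c("m", "i", "d"))
  lp <- log(mt$start[qidx[1]])
  if (length(qidx) > 1)
    lp <- lp + sum(log(mt$trans[cbind(qidx[-length(qidx)], qidx[-1])]))
  lp <- lp + log(mt$stop)
  i <- 0L; j <- 0L
  for (q in seq_along(states)) {
    if (states[q] == "m") {
      i <- i + 1L; j <- j + 1L
      lp <- lp + log(em$jm[pair$s_idx[i] + 1L, pair$t_idx[j] + 1L])
    } else if (states[q] == "i") {
      i <- i + 1L
      lp <- lp + log(em$gap[pair$s_idx[i] + 1L])
    } else {
      j <- j + 1L
      lp <- lp + log(em$gap[pair$t_idx[j] + 1L])
    }
  }
  unname(-lp / log(2))
}
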