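#' Pairwise alignment as a three-state string
#'
#' An alignment of a sequence pair is represented by its state string over
#' `m` (match), `i` (insert: consumes a residue of S) and `d` (delete:
#' consumes a residue of T), equivalently a source-to-sink path in the
#' `(|S|+1) x (|T|+1)` alignment matrix.
#'
#' @param states character scalar over `{m, i, d}`.
#' @param s_length,t_length lengths of the two sequences the alignment refers
#'   to; checked against the state counts (`#m + #i = |S|`, `#m + #d = |T|`).
#' @return an object of class `pairwise_alignment`.
#' @export
#' @examples
#' a <- pairwise_alignment("mmidm", 4, 4)
#' diagonal_profile(a)
pairwise_alignment <- function(states, s_length, t_length) {
  if (length(states) != 1 || !is.character(states))
    stop("states must be a single character string")
  ch <- strsplit(states, "", fixed = TRUE)[[1]]
  if (length(ch) == 0 || !all(ch %in% c("m", "i", "d")))
    stop("alignment state string may contain only 'm', 'i' and 'd'")
  nm <- sum(ch == "m"); ni <- sum(ch == "i"); nd <- sum(ch == "d")
  if (nm + ni != s_length || nm + nd != t_length)
    stop(sprintf("state string (m=%d, i=%d, d=%d) is inconsistent with lengths |S|=%d, |T|=%d",
                 nm, ni, nd, s_length, t_length))
  structure(list(states = states, s_length = as.integer(s_length),
                 t_length = as.integer(t_length)),
            class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("pairwise_alignment |S|=%d |T|=%d, %d columns\n",
              x$s_length, x$t_length, nchar(x$states)))
  cat(" ", x$states, "\n")
  invisible(x)
}

#' Skew-diagonal crossing profile of an alignment path
#'
#' Every source-to-sink path crosses each skew diagonal `k = i + j`,
#' `k = 0..|S|+|T|`, exactly once. This returns the signed proper-diagonal
#' index `j - i` at which the path crosses each skew diagonal. A diagonal
#' (match) move from `(i-1, j-1)` to `(i, j)` cuts across two skew diagonals,
#' `i+j-1` and `i+j`, both at the move's constant proper diagonal `j - i`;
#' insert and delete moves set the profile at the new cell's skew index only.
#'
#' @param a a `pairwise_alignment`.
#' @return integer vector of length `|S|+|T|+1`; element `k+1` is the proper
#'   diagonal at skew diagonal `k`. Always starts at 0 and ends at
#'   `|T|-|S|`, with steps of at most 1 in absolute value.
#' @export
diagonal_profile <- function(a) {
  stopifnot(inherits(a, "pairwise_alignment"))
  ch <- strsplit(a$states, "", fixed = TRUE)[[1]]
  total <- a$s_length + a$t_length
  pi_k <- integer(total + 1)
  i <- 0L; j <- 0L
  for (s in ch) {
    if (s == "m") {
      i <- i + 1L; j <- j + 1L
      pi_k[i + j] <- j - i        # skew i+j-1 (1-based index i+j)
      pi_k[i + j + 1L] <- j - i   # skew i+j
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

#' Distance between two alignments of the same pair
#'
#' The area-like inter-alignment distance: the sum over all skew diagonals of
#' the absolute difference of the two paths' proper-diagonal crossing indices
#' (the "width" between the paths at each skew diagonal). Zero exactly when
#' the state strings are identical; symmetric; satisfies the triangle
#' inequality (it is an L1 distance between crossing profiles).
#'
#' @param a1,a2 `pairwise_alignment` objects for the same sequence lengths.
#' @return non-negative integer distance.
#' @seealso [normalized_distance()] for the length-calibrated value.
#' @export
#' @examples
#' alignment_distance(pairwise_alignment("mm", 2, 2),
#'                    pairwise_alignment("iidd", 2, 2))  # 4
alignment_distance <- function(a1, a2) {
  stopifnot(inherits(a1, "pairwise_alignment"), inherits(a2, "pairwise_alignment"))
  if (a1$s_length != a2$s_length || a1$t_length != a2$t_length)
    stop("alignments refer to different sequence lengths")
  sum(abs(diagonal_profile(a1) - diagonal_profile(a2)))
}

#' Normalize an inter-alignment distance by the pair's length
#'
#' Divides a raw distance by `|S| + |T|`, the maximum possible number of
#' columns of any alignment of the pair, so distances are comparable across
#' pairs of different lengths.
#'
#' @param d non-negative raw distance.
#' @param m,n the sequence lengths.
#' @return `d / (m + n)`.
#' @export
normalized_distance <- function(d, m, n) {
  if (any(d < 0)) stop("distance must be non-negative")
  if (m < 1 || n < 1) stop("sequence lengths must be at least 1")
  d / (m + n)
}

#' Convert a gapped pairwise alignment to a state string
#'
#' @param s_gapped,t_gapped equal-length aligned strings with `-` gaps.
#' @param strict if `TRUE` (default), a column gapped in both sequences is an
#'   error; if `FALSE` such columns are dropped with a warning.
#' @return a `pairwise_alignment`.
#' @export
gapped_to_alignment <- function(s_gapped, t_gapped, strict = TRUE) {
  cs <- strsplit(s_gapped, "", fixed = TRUE)[[1]]
  ct <- strsplit(t_gapped, "", fixed = TRUE)[[1]]
  if (length(cs) != length(ct))
    stop("gapped sequences must have equal lengths")
  both <- cs == "-" & ct == "-"
  if (any(both)) {
    if (strict)
      stop(sprintf("column %d is gapped in both sequences (strict mode)", which(both)[1]))
    warning(sprintf("dropped %d column(s) gapped in both sequences", sum(both)), call. = FALSE)
    cs <- cs[!both]; ct <- ct[!both]
  }
  states <- ifelse(cs != "-" & ct != "-", "m", ifelse(ct == "-", "i", "d"))
  pairwise_alignment(paste(states, collapse = ""),
                     sum(cs != "-"), sum(ct != "-"))
}

#' Render an alignment as gapped sequence strings
#'
#' @param a a `pairwise_alignment`.
#' @param pair the `sequence_pair` the alignment refers to.
#' @return character vector of two equal-length gapped strings.
#' @export
alignment_to_gapped <- function(a, pair) {
  stopifnot(inherits(a, "pairwise_alignment"), inherits(pair, "sequence_pair"))
  if (a$s_length != pair$s_length || a$t_length != pair$t_length)
    stop("alignment is inconsistent with the pair's sequence lengths")
  ch <- strsplit(a$states, "", fixed = TRUE)[[1]]
  s_res <- strsplit(pair$s, "", fixed = TRUE)[[1]]
  t_res <- strsplit(pair$t, "", fixed = TRUE)[[1]]
  i <- 0L; j <- 0L
  gs <- gt <- character(length(ch))
  for (k in seq_along(ch)) {
    if (ch[k] != "d") { i <- i + 1L; gs[k] <- s_res[i] } else gs[k] <- "-"
    if (ch[k] != "i") { j <- j + 1L; gt[k] <- t_res[j] } else gt[k] <- "-"
  }
  c(paste(gs, collapse = ""), paste(gt, collapse = ""))
}
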