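# The 20-letter amino-acid alphabet and the residue-resolution policy.
# Index 21 (0-based 20) is the augmented slot for 'X', encoded by
# stationary-expected probabilities; see emission_tables().

AA_SYMBOLS <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                "L", "K", "M", "F", "P", "S", "T", "W", "V", "Y")

# direct resolutions of ambiguity / nonstandard one-letter codes
AA_AMBIGUITY <- c(B = "D", Z = "E", U = "C", O = "K", J = "L")

X_INDEX <- 20L  # 0-based index of the augmented 'X' emission row/column

#' Amino-acid alphabet
#'
#' The ordered 20-letter amino-acid alphabet used throughout the package,
#' with its symbol-to-index map.
#'
#' @return a list with `symbols` (character vector of length 20) and `index`
#'   (named integer vector mapping symbol to 0-based index).
#' @export
aa_alphabet <- function() {
  list(symbols = AA_SYMBOLS,
       index = setNames(seq_along(AA_SYMBOLS) - 1L, AA_SYMBOLS))
}

# Encode a residue string as 0-based indices. Policy "lenient" resolves
# B/Z/U/O/J to a standard residue and maps X to the augmented slot; "strict"
# rejects anything outside the 20 standard letters.
encode_residues <- function(x, policy = c("lenient", "strict"), what = "sequence") {
  policy <- match.arg(policy)
  chars <- toupper(strsplit(x, "", fixed = TRUE)[[1]])
  if (length(chars) == 0) stop(what, " is empty")
  idx <- match(chars, AA_SYMBOLS) - 1L
  bad <- which(is.na(idx))
  if (length(bad)) {
    if (policy == "strict")
      stop(sprintf("%s contains nonstandard residue '%s' at position %d (strict mode)",
                   what, chars[bad[1]], bad[1]))
    amb <- AA_AMBIGUITY[chars[bad]]
    resolved <- match(amb, AA_SYMBOLS) - 1L
    xpos <- chars[bad] == "X"
    resolved[xpos] <- X_INDEX
    if (anyNA(resolved)) {
      first <- bad[which(is.na(resolved))[1]]
      stop(sprintf("%s contains unknown residue '%s' at position %d",
                   what, chars[first], first))
    }
    idx[bad] <- resolved
    warning(sprintf("%s: resolved %d nonstandard residue(s) (%s)",
                    what, length(bad),
                    paste(unique(chars[bad]), collapse = ",")), call. = FALSE)
  }
  idx
}
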