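#' Read a time-parameterized substitution model
#'
#' Parses the plain-text model format bundled with the package: comment lines
#' starting with `#`, one line with the 20 amino-acid symbols in file order,
#' twenty rows of twenty conditional substitution probabilities for one unit of
#' Markov time (rows sum to 1), and a final row with the stationary
#' distribution. Values are whitespace-separated. The matrix is reordered to
#' the package's canonical alphabet.
#'
#' @param path path to a model file.
#' @param name optional label; defaults to the file name.
#' @return an object of class `substitution_model`: a list with `name`,
#'   `base` (20x20 row-stochastic matrix, one unit of Markov time) and
#'   `stationary` (length-20 probability vector), plus an eigendecomposition
#'   cache used by [matrix_at_time()].
#' @seealso [bundled_model()] for the models shipped with the package.
#' @export
read_substitution_model <- function(path, name = NULL) {
  if (!file.exists(path)) stop("model file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) != 22)
    stop("model file must have a symbol line, 20 matrix rows and a stationary row")
  syms <- toupper(strsplit(trimws(lines[1]), "\\s+")[[1]])
  if (length(syms) != 20 || anyDuplicated(syms) || !setequal(syms, AA_SYMBOLS))
    stop("model file symbol line must list the 20 standard amino acids")
  parse_row <- function(ln) as.numeric(strsplit(trimws(ln), "\\s+")[[1]])
  M <- t(vapply(lines[2:21], parse_row, numeric(20)))
  stat <- parse_row(lines[22])
  if (ncol(M) != 20 || length(stat) != 20) stop("model rows must have 20 entries")
  dimnames(M) <- list(syms, syms)
  names(stat) <- syms
  ord <- match(AA_SYMBOLS, syms)
  M <- M[ord, ord]
  stat <- stat[ord]
  substitution_model(M, stat, name = if (is.null(name)) basename(path) else name)
}

#' Construct and validate a substitution model
#'
#' @param base 20x20 conditional probability matrix (rows sum to 1) for one
#'   unit of Markov time, in the canonical alphabet order.
#' @param stationary length-20 stationary distribution; must be a left fixed
#'   point of `base`.
#' @param name label for the model.
#' @return a `substitution_model` object.
#' @export
substitution_model <- function(base, stationary, name = "custom") {
  base <- as.matrix(base)
  stationary <- as.numeric(stationary)
  if (!all(dim(base) == c(20, 20))) stop("base matrix must be 20x20")
  if (any(base < 0) || any(stationary < 0)) stop("probabilities must be non-negative")
  if (any(abs(rowSums(base) - 1) > 1e-12)) stop("rows of base matrix must sum to 1")
  if (abs(sum(stationary) - 1) > 1e-12) stop("stationary distribution must sum to 1")
  if (max(abs(as.vector(stationary %*% base) - stationary)) > 1e-8)
    stop("stationary vector is not a left fixed point of the base matrix")
  dimnames(base) <- list(AA_SYMBOLS, AA_SYMBOLS)
  names(stationary) <- AA_SYMBOLS
  structure(list(name = name, base = base, stationary = stationary,
                 .cache = new.env(parent = emptyenv())),
            class = "substitution_model")
}

#' Bundled substitution models
#'
#' Loads one of the four synthetic time-parameterized models shipped with the
#' package (`"MMLSUM"`, `"PAM"`, `"BLOSUM"`, `"VTML"`, case-insensitive, or the
#' matching `*_like` file names). These are reversible stand-in matrices
#' constructed from physicochemical-class exchangeabilities and calibrated so
#' that the expected-%-change curve follows the published Markov-time scale for
#' this model family (about 1% change at t = 1, at most 71% at t = 150, about
#' 92% at t = 500); they are not the original published matrices. A file path
#' to a custom model in the same format is also accepted.
#'
#' @param name model name or a path to a model file.
#' @return a `substitution_model`.
#' @export
#' @examples
#' m <- bundled_model("MMLSUM")
#' expected_change(m, 150)
bundled_model <- function(name = "MMLSUM") {
  if (file.exists(name)) return(read_substitution_model(name))
  key <- tolower(sub("[_-]?like(\\.txt)?$", "", name))
  files <- c(mmlsum = "mmlsum_like.txt", pam = "pam_like.txt",
             blosum = "blosum_like.txt", vtml = "vtml_like.txt")
  if (!key %in% names(files))
    stop("unknown model '", name, "'; available: ",
         paste(toupper(names(files)), collapse = ", "), " or a file path")
  path <- system.file("extdata", "models", files[[key]], package = "marginalign")
  read_substitution_model(path, name = toupper(key))
}

#' @export
print.substitution_model <- function(x, ...) {
  cat(sprintf("substitution_model '%s' (20x20, one unit of Markov time)\n", x$name))
  cat(sprintf("  expected change: t=1 %.2f%%, t=150 %.2f%%, t=500 %.2f%%\n",
              expected_change(x, 1), expected_change(x, 150), expected_change(x, 500)))
  invisible(x)
}

model_eigen <- function(model) {
  cache <- model$.cache
  if (is.null(cache$eig)) {
    e <- eigen(model$base)
    inv <- tryCatch(solve(e$vectors), error = function(err) NULL)
    cache$eig <- list(values = e$values, vectors = e$vectors, inverse = inv)
  }
  cache$eig
}

# exact integer matrix power by repeated squaring
matrix_int_power <- function(M, k) {
  out <- diag(nrow(M))
  P <- M
  while (k > 0) {
    if (k %% 2 == 1) out <- out %*% P
    P <- P %*% P
    k <- k %/% 2
  }
  out
}

#' Substitution matrix at an arbitrary Markov time
#'
#' Computes `M^t` for the model's base matrix, via eigendecomposition for
#' non-integer `t`. Tiny negative entries produced by numerical error are
#' clamped to zero and the rows renormalized, so the result is always
#' row-stochastic.
#'
#' @param model a `substitution_model`.
#' @param t non-negative Markov time (may be fractional).
#' @return 20x20 row-stochastic matrix.
#' @export
matrix_at_time <- function(model, t) {
  stopifnot(inherits(model, "substitution_model"))
  if (length(t) != 1 || !is.finite(t) || t < 0)
    stop("Markov time t must be a single non-negative number")
  if (t == 0) {
    M <- diag(20)
    dimnames(M) <- dimnames(model$base)
    return(M)
  }
  e <- model_eigen(model)
  if (abs(t - round(t)) < 1e-9) {
    # integer powers by repeated squaring: exact, and the only route for a
    # base matrix whose eigenvector matrix is (numerically) singular
    M <- matrix_int_power(model$base, round(t))
  } else if (is.null(e$inverse)) {
    stop("base matrix is numerically defective; only integer Markov times are supported for it")
  } else {
    M <- Re(e$vectors %*% (as.complex(e$values)^t * e$inverse))
  }
  M[M < 0] <- 0
  M <- M / rowSums(M)
  dimnames(M) <- dimnames(model$base)
  M
}

#' Expected percentage of amino-acid change at a Markov time
#'
#' The model-implied expected fraction of substituted residues after time `t`:
#' `100 * (1 - sum_a stationary[a] * M^t[a, a])`. Monotonically non-decreasing
#' in `t` for the bundled (reversible) models.
#'
#' @param model a `substitution_model`.
#' @param t non-negative Markov time(s); vectorized.
#' @return percentage(s) in `[0, 100]`.
#' @export
expected_change <- function(model, t) {
  stopifnot(inherits(model, "substitution_model"))
  if (any(!is.finite(t)) || any(t < 0)) stop("Markov time t must be non-negative")
  vapply(t, function(tt)
    100 * (1 - sum(model$stationary * diag(matrix_at_time(model, tt)))),
    numeric(1))
}

#' Joint match probability of a residue pair
#'
#' Probability that a matched alignment column holds amino acids `a` (in S)
#' and `b` (in T) at Markov time `t`: `stationary[a] * M^t[a, b]`. Summing
#' over all 400 ordered pairs gives 1.
#'
#' @param model a `substitution_model`.
#' @param t non-negative Markov time.
#' @param a,b one-letter residue codes (standard 20 letters; ambiguity codes
#'   follow the lenient policy of the alphabet).
#' @return a probability.
#' @export
joint_match_probability <- function(model, t, a, b) {
  em <- emission_tables(model, t)
  ia <- encode_residues(a, "lenient", "residue a")
  ib <- encode_residues(b, "lenient", "residue b")
  if (length(ia) != 1 || length(ib) != 1) stop("a and b must be single residues")
  em$jm[ia + 1L, ib + 1L]
}

# Emission tables at time t: 21x21 joint match probabilities (row/col 21 is
# the augmented 'X' slot, the stationary-expected value) and the length-21
# 20-nomial gap emission vector. The gap distribution defaults to the model's
# stationary distribution but can be overridden.
emission_tables <- function(model, t, gap_probs = NULL) {
  M <- matrix_at_time(model, t)
  pi0 <- model$stationary
  jm <- pi0 * M                      # jm[a, b] = pi_a * M^t[a, b]
  jm <- rbind(jm, as.vector(pi0 %*% jm))
  jm <- cbind(jm, as.vector(jm[, 1:20] %*% pi0))
  if (is.null(gap_probs)) gap_probs <- pi0
  if (length(gap_probs) != 20 || abs(sum(gap_probs) - 1) > 1e-9)
    stop("gap_probs must be a length-20 probability vector")
  gp <- c(gap_probs, sum(pi0 * gap_probs))
  list(jm = jm, gap = gp)
}
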