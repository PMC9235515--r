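# FASTA and TSV input/output. FASTA parsing goes through Biostrings.

#' Read a sequence pair from FASTA
#'
#' Accepts either one FASTA file with exactly two records or two files with
#' one record each. Record headers are preserved as metadata and the first
#' header doubles as the pair id.
#'
#' @param path FASTA file (two records, or one record if `path2` is given).
#' @param path2 optional second single-record FASTA file.
#' @param policy residue policy passed to [sequence_pair()].
#' @return a `sequence_pair` with a `headers` attribute.
#' @export
read_pair <- function(path, path2 = NULL, policy = c("lenient", "strict")) {
  policy <- match.arg(policy)
  seqs <- Biostrings::readBStringSet(path)
  if (!is.null(path2)) {
    if (length(seqs) != 1)
      stop("file '", path, "' must hold exactly one record when two files are given")
    seqs <- c(seqs, Biostrings::readBStringSet(path2))
  }
  if (length(seqs) != 2)
    stop("file '", path, "' must hold exactly two records (found ", length(seqs), ")")
  if (any(Biostrings::width(seqs) == 0))
    stop("file '", path, "' contains an empty sequence")
  pair <- sequence_pair(as.character(seqs[[1]]), as.character(seqs[[2]]),
                        id = names(seqs)[1], policy = policy)
  attr(pair, "headers") <- names(seqs)
  pair
}

#' Read a reference alignment in gapped pairwise FASTA
#'
#' Reads a two-record gapped FASTA (equal record widths, `-` gaps), checks
#' that the ungapped sequences match the pair exactly, and converts to a
#' three-state alignment.
#'
#' @param path gapped pairwise FASTA file.
#' @param pair the `sequence_pair` the alignment must refer to.
#' @param strict if `TRUE` (default) a column gapped in both records is an
#'   error; otherwise such columns are dropped with a warning.
#' @return a `pairwise_alignment`.
#' @export
read_reference_alignment <- function(path, pair, strict = TRUE) {
  stopifnot(inherits(pair, "sequence_pair"))
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) != 2)
    stop("reference alignment '", path, "' must hold exactly two records")
  g1 <- toupper(as.character(seqs[[1]]))
  g2 <- toupper(as.character(seqs[[2]]))
  check_ungapped <- function(gapped, expected, label) {
    ung <- gsub("-", "", gapped, fixed = TRUE)
    if (nchar(ung) != nchar(expected))
      stop(sprintf("ungapped %s of the reference (%d residues) does not match the pair (%d)",
                   label, nchar(ung), nchar(expected)))
    u <- strsplit(ung, "")[[1]]; e <- strsplit(toupper(expected), "")[[1]]
    bad <- which(u != e)
    if (length(bad))
      stop(sprintf("reference %s differs from the pair at position %d ('%s' vs '%s')",
                   label, bad[1], u[bad[1]], e[bad[1]]))
  }
  check_ungapped(g1, pair$s, "S")
  check_ungapped(g2, pair$t, "T")
  gapped_to_alignment(g1, g2, strict = strict)
}

#' Write comparison results as TSV
#'
#' Writes one row per comparison with a stable column order and display
#' precisions of one decimal for bit quantities and three decimals for
#' normalized distances. Provenance (model, machine configuration hash,
#' package version) is embedded as `#` comment lines, so a result file is
#' sufficient to re-run the computation.
#'
#' @param results an `mml_comparison`, or a list of them; each may carry an
#'   `expected_distance` element (as produced by
#'   [expected_alignment_distance()]) to fill the E.A.D. column.
#' @param path output file.
#' @param model,machine optional objects recorded in the provenance header.
#' @return the path, invisibly.
#' @export
write_results <- function(results, path, model = NULL, machine = NULL) {
  if (inherits(results, "mml_comparison")) results <- list(results)
  fmt1 <- function(x) ifelse(is.na(x), NA, sprintf("%.1f", x))
  fmt3 <- function(x) ifelse(is.na(x), NA, sprintf("%.3f", x))
  grab <- function(r, f) if (is.null(r[[f]])) NA_real_ else r[[f]]
  df <- do.call(rbind, lapply(results, function(r) {
    ead <- r$expected_distance
    data.frame(pair = grab(r, "pair_id"),
               s_length = grab(r, "s_length"),
               t_length = grab(r, "t_length"),
               null_bits = fmt1(grab(r, "null_bits")),
               i_optimal_bits = fmt1(grab(r, "i_optimal_bits")),
               i_marginal_bits = fmt1(grab(r, "i_marginal_bits")),
               delta_optimal = fmt1(grab(r, "delta_optimal_bits")),
               delta_marginal = fmt1(grab(r, "delta_marginal_bits")),
               time_optimal = fmt1(grab(r, "time_optimal")),
               time_marginal = fmt1(grab(r, "time_marginal")),
               expected_distance = fmt3(if (is.null(ead)) NA_real_ else ead$normalized))
  }))
  if (is.null(df)) {
    df <- data.frame(pair = character(), s_length = integer(), t_length = integer(),
                     null_bits = character(), i_optimal_bits = character(),
                     i_marginal_bits = character(), delta_optimal = character(),
                     delta_marginal = character(), time_optimal = character(),
                     time_marginal = character(), expected_distance = character())
  }
  cfg <- paste(if (is.null(model)) "model=NA" else paste0("model=", model$name),
               if (is.null(machine)) "machine=NA" else
                 paste0("machine=", paste(format(unlist(machine[!vapply(machine, is.function, TRUE)])),
                                          collapse = ",")),
               sep = "; ")
  df$config <- rep(config_hash(cfg), nrow(df))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# marginalign %s results", as.character(utils::packageVersion("marginalign"))),
               paste0("# ", cfg)), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a results TSV written by [write_results()]
#'
#' @param path TSV file.
#' @return data frame.
#' @export
read_results <- function(path) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Write a simulated pair (and its true alignment) to FASTA
#'
#' Writes `<prefix>.fasta` with the two sequences and
#' `<prefix>_true_alignment.fasta` with the gapped true alignment.
#'
#' @param sp a `simulated_pair`.
#' @param prefix output path prefix.
#' @return character vector of the two paths, invisibly.
#' @export
write_simulated_pair <- function(sp, prefix) {
  stopifnot(inherits(sp, "simulated_pair"))
  p1 <- paste0(prefix, ".fasta")
  p2 <- paste0(prefix, "_true_alignment.fasta")
  ids <- c(paste0(sp$pair$id, "_S"), paste0(sp$pair$id, "_T"))
  seqs <- Biostrings::BStringSet(setNames(c(sp$pair$s, sp$pair$t), ids))
  Biostrings::writeXStringSet(seqs, p1)
  gapped <- alignment_to_gapped(sp$true_alignment, sp$pair)
  aln <- Biostrings::BStringSet(setNames(gapped, ids))
  Biostrings::writeXStringSet(aln, p2)
  invisible(c(p1, p2))
}
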