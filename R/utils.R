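# Shared constants and small helpers. Coordinates are 1-based inclusive
# throughout the package, matching the formats parsed.

#' @importFrom stats setNames aggregate median rnorm runif
#' @importFrom utils data
NULL

#' Amino-acid alphabets
#'
#' `AA20` is the standard 20-letter amino-acid alphabet in alphabetical
#' order; `AA_WITH_X` additionally allows the undetermined residue `X`.
#'
#' @format Character vectors of single letters.
#' @name alphabets
#' @keywords internal
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' @rdname alphabets
#' @keywords internal
AA_WITH_X <- c(AA20, "X")

# Kyte-Doolittle hydropathy scale (kcal-free index, positive = hydrophobic).
KD_SCALE <- c(
  A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
  L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2,
  X =  0.0
)

# Van der Waals radii (Angstrom) used by the cavity detector.
VDW_RADII <- c(C = 1.7, N = 1.55, O = 1.52, S = 1.8)
VDW_DEFAULT <- 1.7

split_residues <- function(seq) strsplit(seq, "", fixed = TRUE)[[1]]

check_residues <- function(seq, allow_x = TRUE, what = "sequence") {
  allowed <- if (allow_x) AA_WITH_X else AA20
  bad <- setdiff(unique(split_residues(seq)), allowed)
  if (length(bad) > 0) {
    stop(sprintf("invalid residue(s) in %s: %s", what,
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

#' Write a data frame as a TSV file
#'
#' Plain tab-separated output with a header row, no quoting and no row
#' names, so report bundles are diffable and byte-stable across runs.
#'
#' @param x A data frame.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a TSV file written by this package
#'
#' @param path File path.
#' @return A data frame.
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, comment.char = "")
}

# Maximal runs of TRUE in a logical vector -> data.frame(start, end, length).
logical_runs <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep],
             length = r$lengths[keep])
}

#' Read protein sequences from a FASTA file
#'
#' Wraps [Biostrings::readAAStringSet()]. The first whitespace-separated
#' token of each header is the sequence id; an optional second token is
#' kept as the taxon label (the convention used by the fixture writers).
#'
#' @param path FASTA file path.
#' @return A data frame with columns `id`, `taxon` (NA when absent) and
#'   `seq`.
#' @export
read_fasta_records <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  headers <- names(ss)
  toks <- strsplit(headers, "[ \t]+")
  id <- vapply(toks, `[`, "", 1L)
  taxon <- vapply(toks, function(t) if (length(t) >= 2) t[2] else NA_character_, "")
  data.frame(id = id, taxon = taxon,
             seq = as.character(ss), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Write protein sequences to a FASTA file
#'
#' @param ids Sequence ids.
#' @param seqs Residue strings.
#' @param path Output path.
#' @param taxa Optional taxon labels appended to the headers.
#' @return Invisibly, `path`.
#' @export
write_fasta_records <- function(ids, seqs, path, taxa = NULL) {
  headers <- if (is.null(taxa)) ids else paste(ids, taxa)
  ss <- Biostrings::AAStringSet(setNames(seqs, headers))
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}
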