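#' Needleman-Wunsch scoring parameters
#'
#' Scoring scheme for affine-gap global alignment. A gap run of length `k`
#' costs `gap_open + (k - 1) * gap_extend`: the opening score covers the
#' first gapped column. Defaults are the conventional amplicon-comparison
#' setting (match 2, mismatch -3, gap open -5, gap extend -2).
#'
#' @param match Score for an identical pair of residues.
#' @param mismatch Score for a non-identical pair.
#' @param gap_open Score of the first column of a gap run (negative).
#' @param gap_extend Score of each subsequent gap column (negative).
#' @return An object of class `nw_scoring`.
#' @export
nw_scoring <- function(match = 2, mismatch = -3, gap_open = -5,
                       gap_extend = -2) {
  stopifnot(is.numeric(match), is.numeric(mismatch),
            is.numeric(gap_open), is.numeric(gap_extend))
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend),
            class = "nw_scoring")
}

#' @export
print.nw_scoring <- function(x, ...) {
  cat(sprintf("NW scoring: match %g, mismatch %g, gap open %g, gap extend %g\n",
              x$match, x$mismatch, x$gap_open, x$gap_extend))
  invisible(x)
}

#' Affine-gap global alignment of two sequences
#'
#' Optimal global alignment under the Gotoh three-state recursion. The
#' traceback is deterministic: at score ties the diagonal (substitution)
#' state is preferred over a gap in the second sequence, which is preferred
#' over a gap in the first.
#'
#' @param a,b Sequences (character scalars or Biostrings objects).
#' @param scoring An [nw_scoring()] object.
#' @return An object of class `nw_alignment`: a list with `aligned_a`,
#'   `aligned_b` (gapped strings of equal length), `score` (the DP optimum)
#'   and `distance` (fraction of alignment columns that are not an identical
#'   unambiguous base pair, in `[0, 1]`).
#' @examples
#' nw_align("ACGT", "AGT")
#' @export
nw_align <- function(a, b, scoring = nw_scoring()) {
  sa <- as_seq_string(a)
  sb <- as_seq_string(b)
  if (nchar(sa) == 0L || nchar(sb) == 0L)
    stop("cannot align empty sequences")
  r <- nw_align_cpp(sa, sb, scoring$match, scoring$mismatch,
                    scoring$gap_open, scoring$gap_extend)
  structure(r, class = "nw_alignment")
}

#' @export
print.nw_alignment <- function(x, ...) {
  cat(x$aligned_a, "\n", x$aligned_b, "\n", sep = "")
  cat(sprintf("score %g, distance %.4f\n", x$score, x$distance))
  invisible(x)
}

#' Alignment distance between two sequences
#'
#' The normalized dissimilarity used as the regression target for embedding
#' training: `1 - (identical columns) / (alignment length)` computed from
#' the optimal global alignment. A column counts as identical only when both
#' residues are the same unambiguous base. Symmetric; 0 iff the sequences
#' are identical.
#'
#' @inheritParams nw_align
#' @return A number in `[0, 1]`.
#' @export
alignment_distance <- function(a, b, scoring = nw_scoring()) {
  nw_align(a, b, scoring)$distance
}

#' Alignment distances for many index pairs
#'
#' Computes the alignment distance (and score) for each requested pair of
#' sequences in one compiled pass.
#'
#' @param seqs Sequences (character vector or [Biostrings::DNAStringSet]).
#' @param pairs Two-column integer matrix or data frame of 1-based indices
#'   into `seqs`.
#' @inheritParams nw_align
#' @return A data frame with columns `a`, `b`, `score`, `distance`.
#' @export
alignment_distances <- function(seqs, pairs, scoring = nw_scoring()) {
  chars <- as_seq_chars(seqs)
  pairs <- as.matrix(pairs[, 1:2])
  storage.mode(pairs) <- "integer"
  if (nrow(pairs) == 0L)
    return(data.frame(a = integer(0), b = integer(0),
                      score = numeric(0), distance = numeric(0)))
  if (min(pairs) < 1L || max(pairs) > length(chars))
    stop("pair indices out of range")
  r <- nw_pairs_cpp(unname(chars), pairs[, 1L], pairs[, 2L],
                    scoring$match, scoring$mismatch,
                    scoring$gap_open, scoring$gap_extend)
  data.frame(a = pairs[, 1L], b = pairs[, 2L],
             score = r$score, distance = r$distance)
}

#' Hard approximate string matching
#'
#' Finds the contiguous subsequence of `seq` with minimum edit distance to
#' `pattern` via the classic DP whose first row is zero (free start) and
#' whose optimum is the maximum of the last row (free end). Ties at the
#' last-row argmax are broken toward the smallest column; branch ties in the
#' traceback are broken diagonal > up > left.
#'
#' @param pattern A short sequence (the query motif).
#' @param seq The sequence to scan.
#' @return A list with `min_edit_distance` (integer in `[0, M]`) and `span`,
#'   the 1-based inclusive interval of the best-matched subsequence (empty,
#'   i.e. `span[1] > span[2]`, when the optimum deletes the whole pattern).
#' @examples
#' hard_asm("ACG", "TTACGTT")
#' @export
hard_asm <- function(pattern, seq) {
  p <- as_seq_string(pattern)
  s <- as_seq_string(seq)
  if (nchar(p) == 0L || nchar(s) == 0L)
    stop("pattern and sequence must be nonempty")
  hard_asm_cpp(p, s)
}

#' Brute-force oracle for approximate string matching
#'
#' Independent check for [hard_asm()]: the minimum, over every contiguous
#' window of `seq` (including the empty window), of the textbook edit
#' distance between `pattern` and the window, using [utils::adist()].
#' Quadratic in the window count, so only suitable for small instances.
#'
#' @inheritParams hard_asm
#' @return The minimum edit distance (nonnegative integer).
#' @export
brute_force_asm_oracle <- function(pattern, seq) {
  p <- as_seq_string(pattern)
  s <- as_seq_string(seq)
  M <- nchar(p)
  L <- nchar(s)
  best <- M  # empty window: delete the whole pattern
  for (start in seq_len(L)) {
    windows <- substring(s, start, start:L)
    best <- min(best, utils::adist(p, windows))
  }
  as.integer(best)
}
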