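#' Sample sequences and enumerate all pairwise alignment distances
#'
#' Draws `n` sequences without replacement, enumerates all `n * (n - 1) / 2`
#' unordered pairs, and (optionally) computes the alignment distance of
#' every pair. This is the evaluation protocol used to score an
#' alignment-free estimator against exhaustive NW ground truth.
#'
#' @param seqs Sequences (character vector or [Biostrings::DNAStringSet]).
#' @param n Number of sequences to draw (`n <= length(seqs)`).
#' @param seed Integer seed for the draw.
#' @param scoring An [nw_scoring()] object.
#' @param distances If FALSE, skip the (possibly expensive) distance
#'   computation and return `NA` distances.
#' @return A list of class `pair_sample` with `indices` (the drawn sequence
#'   indices), `sequences` (their residues) and `pairs` (data frame with
#'   columns `a`, `b` -- indices into `sequences` -- and `d_a`).
#' @export
sample_pairs <- function(seqs, n, seed = 1L, scoring = nw_scoring(),
                         distances = TRUE) {
  chars <- as_seq_chars(seqs)
  if (n > length(chars))
    stop("cannot sample ", n, " sequences from ", length(chars))
  stopifnot(n >= 2L)
  set.seed(seed)
  idx <- sample.int(length(chars), n)
  sel <- chars[idx]
  pr <- t(utils::combn(n, 2L))
  if (distances) {
    d <- alignment_distances(sel, pr, scoring)$distance
  } else {
    d <- rep(NA_real_, nrow(pr))
  }
  structure(list(indices = idx, sequences = sel,
                 pairs = data.frame(a = pr[, 1L], b = pr[, 2L], d_a = d)),
            class = "pair_sample")
}

#' Mean relative error, in percent
#'
#' `mean(|estimated - truth| / truth) * 100` over the pairs with positive
#' true distance. Pairs with `truth == 0` have undefined relative error and
#' are excluded; their count is reported in the `n_excluded` attribute.
#'
#' @param estimated,truth Numeric vectors of equal length.
#' @return The MRE as a percentage (plain number, e.g. `4.5` for 4.5%),
#'   with attribute `n_excluded`.
#' @examples
#' mre(c(0.1, 0.3), c(0.1, 0.2))  # 25%
#' @export
mre <- function(estimated, truth) {
  stopifnot(length(estimated) == length(truth), length(truth) >= 1L)
  keep <- truth > 0
  if (!any(keep))
    stop("mean relative error is undefined: all true distances are zero")
  out <- mean(abs(estimated[keep] - truth[keep]) / truth[keep]) * 100
  attr(out, "n_excluded") <- sum(!keep)
  out
}

#' Nearest-neighbour taxonomy assignment
#'
#' Labels each query with the label of the reference sequence whose
#' embedding is nearest in cosine distance (ties toward the smallest
#' reference index), and compares against the NW ground truth: the label of
#' the reference with maximum alignment score (ties likewise). Reference
#' embeddings are computed exactly once.
#'
#' @param queries Query sequences.
#' @param refs Reference sequences.
#' @param labels Character vector of reference labels (genus-like), one per
#'   reference, all nonempty.
#' @param params A trained [pattern_set()].
#' @param scoring An [nw_scoring()] object for the ground-truth search.
#' @param ref_embeddings Optional precomputed matrix from
#'   `embed_sequences(refs, params)`.
#' @return A list with `labels` (predicted), `truth` (NW-derived) and
#'   `accuracy` (fraction of agreement).
#' @export
assign_taxonomy <- function(queries, refs, labels, params,
                            scoring = nw_scoring(), ref_embeddings = NULL) {
  qc <- as_seq_chars(queries)
  rc <- as_seq_chars(refs)
  stopifnot(length(rc) >= 1L, length(labels) == length(rc),
            all(nzchar(labels)))
  if (is.null(ref_embeddings)) ref_embeddings <- embed_sequences(rc, params)
  qe <- embed_sequences(qc, params)
  pred <- vapply(seq_len(nrow(qe)), function(i) {
    d <- vapply(seq_len(nrow(ref_embeddings)),
                function(j) cosine_distance(qe[i, ], ref_embeddings[j, ]),
                numeric(1))
    which.min(d)  # which.min takes the first minimum: smallest index wins
  }, integer(1))
  scores <- nw_score_matrix_cpp(unname(qc), unname(rc), scoring$match,
                                scoring$mismatch, scoring$gap_open,
                                scoring$gap_extend)
  truth <- apply(scores, 1L, which.max)
  list(labels = labels[pred], truth = labels[truth],
       accuracy = mean(labels[pred] == labels[truth]))
}
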