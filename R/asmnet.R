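#' Smoothed maximum operator
#'
#' The generalized maximum `soft_max_gamma(a, gamma) = gamma * log(sum(
#' exp(a / gamma)))`, a smooth upper bound on the hard maximum that
#' converges to it as `gamma` tends to 0. Computed with max-subtraction so
#' it is stable for arbitrarily large magnitudes. Satisfies
#' `max(a) <= soft_max_gamma(a, gamma) <= max(a) + gamma * log(length(a))`.
#'
#' @param values Nonempty numeric vector.
#' @param gamma Positive smoothing parameter.
#' @return A single number.
#' @examples
#' soft_max_gamma(c(0, 0, 0), 1)   # log(3)
#' soft_max_gamma(c(5, -1000), 0.1)
#' @export
soft_max_gamma <- function(values, gamma) {
  stopifnot(length(values) >= 1L, is.numeric(values), gamma > 0)
  mx <- max(values)
  mx + gamma * log(sum(exp((values - mx) / gamma)))
}

#' Learnable pattern set for the soft ASM layer
#'
#' Container for the parameters of the embedding network: `N` pattern
#' matrices (each `M x 4`, unconstrained reals), a shared positive gap
#' penalty `g`, a bias vector `b` of length `N`, and the smoothing
#' parameter `gamma`. The alphabet column order is recorded so that
#' serialized models are portable.
#'
#' @param patterns An `M x 4 x N` numeric array of pattern matrices.
#' @param gap Positive gap penalty shared across patterns.
#' @param bias Numeric vector of length `N`.
#' @param gamma Positive smoothing parameter of the soft maximum.
#' @return An object of class `pattern_set`.
#' @seealso [random_pattern_set()] for seeded random initialization.
#' @export
pattern_set <- function(patterns, gap = 1, bias = NULL, gamma = 0.1) {
  patterns <- as.array(patterns)
  if (length(dim(patterns)) == 2L) dim(patterns) <- c(dim(patterns), 1L)
  stopifnot(length(dim(patterns)) == 3L, dim(patterns)[2L] == 4L,
            dim(patterns)[1L] >= 1L, dim(patterns)[3L] >= 1L,
            gap > 0, gamma > 0)
  n <- dim(patterns)[3L]
  if (is.null(bias)) bias <- numeric(n)
  stopifnot(length(bias) == n)
  structure(list(patterns = patterns, gap = as.numeric(gap),
                 bias = as.numeric(bias), gamma = as.numeric(gamma),
                 alphabet = c("A", "C", "G", "T"),
                 format_version = 1L),
            class = "pattern_set")
}

#' Random pattern-set initialization
#'
#' Patterns are drawn i.i.d. uniform on (0, 1), the gap penalty starts at 1
#' and the bias at 0 -- the initialization used by [train_asmatch()].
#'
#' @param n_patterns Number of patterns `N`.
#' @param pattern_len Pattern length `M`.
#' @param gamma Smoothing parameter.
#' @param seed Integer seed (optional; uses the current RNG state if NULL).
#' @return A `pattern_set`.
#' @export
random_pattern_set <- function(n_patterns, pattern_len, gamma = 0.1,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  patterns <- array(stats::runif(pattern_len * 4 * n_patterns),
                    dim = c(pattern_len, 4L, n_patterns))
  pattern_set(patterns, gap = 1, bias = numeric(n_patterns), gamma = gamma)
}

#' @export
print.pattern_set <- function(x, ...) {
  d <- dim(x$patterns)
  cat(sprintf("pattern_set: N = %d patterns of length M = %d, g = %.4g, gamma = %.4g\n",
              d[3L], d[1L], x$gap, x$gamma))
  invisible(x)
}

#' Soft ASM forward pass for one pattern
#'
#' Fills the `(M+1) x (L+1)` scoring matrix of the smoothed
#' approximate-string-matching recursion: the first row is zero (matching
#' may start anywhere), the first column is `-m * g`, and each interior cell
#' combines the diagonal branch (`F[m-1, l-1] + p_m . s_l`), the up branch
#' (`F[m-1, l] - g`) and the left branch (`F[m, l-1] - g`) with the
#' smoothed maximum. The score `v` is the hard maximum over the last row
#' (ties toward the smallest column); the smoothing applies only inside the
#' recursion.
#'
#' @param P An `M x 4` pattern matrix.
#' @param S An `L x 4` one-hot sequence matrix (see [one_hot_encode()]).
#' @param g Positive gap penalty.
#' @param gamma Positive smoothing parameter.
#' @return An object of class `soft_score_matrix`: list with `F` (the
#'   `(M+1) x (L+1)` matrix), `v` (last-row maximum) and `argmax_col`
#'   (0-based column of that maximum, i.e. number of sequence positions
#'   consumed).
#' @export
soft_asm_forward <- function(P, S, g, gamma) {
  P <- as.matrix(P)
  S <- as.matrix(S)
  stopifnot(ncol(P) == 4L, ncol(S) == 4L, g > 0, gamma > 0)
  r <- soft_asm_cpp(P, S, g, gamma)
  structure(r, class = "soft_score_matrix")
}

#' Hard-max ASM score (smoothing-free reference recursion)
#'
#' The same recursion as [soft_asm_forward()] with the exact maximum in
#' place of the smoothed one; the limit of the soft score as `gamma` tends
#' to 0. Pure R, intended for small instances and as a numerical
#' cross-check.
#'
#' @inheritParams soft_asm_forward
#' @return The hard-max score `v` (maximum of the last row).
#' @export
hard_max_asm_score <- function(P, S, g) {
  P <- as.matrix(P)
  S <- as.matrix(S)
  M <- nrow(P)
  L <- nrow(S)
  if (M == 0L) return(0)  # boundary row only
  R <- P %*% t(S)
  F <- matrix(0, M + 1L, L + 1L)
  F[, 1L] <- -(0:M) * g
  F[1L, ] <- 0
  for (l in seq_len(L)) {
    for (m in seq_len(M)) {
      F[m + 1L, l + 1L] <- max(F[m, l] + R[m, l],
                               F[m, l + 1L] - g,
                               F[m + 1L, l] - g)
    }
  }
  max(F[M + 1L, ])
}

#' Best-match span from a soft scoring matrix
#'
#' Backtracks from `(M, argmax_col)` choosing at each cell the branch whose
#' argument is largest (ties diagonal > up > left) until row 0 is reached.
#' The consumed columns form the best-matched subsequence used for gradient
#' computation.
#'
#' @param F A `soft_score_matrix` from [soft_asm_forward()].
#' @param g,gamma The parameters used to produce `F`.
#' @param P,S The pattern and one-hot sequence used to produce `F`.
#' @return Integer vector `c(start, end)`, a 1-based inclusive interval into
#'   the sequence; empty when `start > end` (the optimum deletes the whole
#'   pattern).
#' @export
best_match_span <- function(F, g, gamma, P, S) {
  if (inherits(F, "soft_score_matrix")) {
    lstar <- F$argmax_col
    Fm <- F$F
  } else {
    Fm <- as.matrix(F)
    last <- Fm[nrow(Fm), ]
    lstar <- which.max(last) - 1L
  }
  R <- as.matrix(P) %*% t(as.matrix(S))
  m <- nrow(Fm) - 1L
  l <- lstar
  while (m > 0L) {
    if (l == 0L) { m <- m - 1L; next }
    diag <- Fm[m, l] + R[m, l]
    up <- Fm[m, l + 1L] - g
    left <- Fm[m + 1L, l] - g
    if (diag >= up && diag >= left) { m <- m - 1L; l <- l - 1L }
    else if (up >= left) m <- m - 1L
    else l <- l - 1L
  }
  c(l + 1L, lstar)
}

#' Embed a sequence with a pattern set
#'
#' Runs the soft ASM forward pass of every pattern against the sequence,
#' extracts the last-row maximum `v_n` per pattern, and returns the
#' nonnegative embedding `u = ReLU(v + b)`. Variable-length sequences are
#' handled natively (no padding); the embedding dimension is always `N`.
#'
#' @param seq A single sequence.
#' @param params A [pattern_set()].
#' @param details If TRUE, also return the raw scores `v` and the per-pattern
#'   best-match spans.
#' @return A numeric vector of length `N`, or (with `details = TRUE`) a list
#'   with `u`, `v` and `spans` (an `N x 2` matrix of 1-based intervals).
#' @export
embed <- function(seq, params, details = FALSE) {
  stopifnot(inherits(params, "pattern_set"))
  S <- one_hot_encode(seq)
  r <- embed_cpp(params$patterns, S, params$gap, params$bias, params$gamma,
                 details)
  if (!details) return(as.numeric(r$u))
  list(u = as.numeric(r$u), v = as.numeric(r$v), spans = r$spans)
}

#' Embed many sequences
#'
#' @param seqs Sequences (character vector or [Biostrings::DNAStringSet]).
#' @param params A [pattern_set()].
#' @return A numeric matrix with one row per sequence and `N` columns,
#'   rownames taken from the sequence ids.
#' @export
embed_sequences <- function(seqs, params) {
  stopifnot(inherits(params, "pattern_set"))
  chars <- as_seq_chars(seqs)
  Slist <- lapply(chars, one_hot_encode)
  out <- embed_batch_cpp(unname(Slist), params$patterns, params$gap,
                         params$bias, params$gamma)
  rownames(out) <- names(chars)
  out
}
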