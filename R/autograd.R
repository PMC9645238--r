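#' Differentiable NW forward pass on a best-matched subsequence
#'
#' Global variant of the soft recursion used for gradient computation: both
#' boundaries are penalized (`F[0, l] = -l * g` as well as
#' `F[m, 0] = -m * g`), so `F[M, L]` approximates the soft ASM score `v`
#' when the input is the extracted best-match span.
#'
#' @param P An `M x 4` pattern matrix.
#' @param S_tilde One-hot matrix of the best-matched subsequence (may have
#'   zero rows for an empty span).
#' @param g,gamma Gap penalty and smoothing parameter.
#' @return The `(M+1) x (L+1)` scoring matrix.
#' @export
diff_nw_forward <- function(P, S_tilde, g, gamma) {
  P <- as.matrix(P)
  S_tilde <- as.matrix(S_tilde)
  if (nrow(S_tilde) == 0L)
    return(matrix(-(0:nrow(P)) * g, nrow(P) + 1L, 1L))
  diff_nw_cpp(P, S_tilde, g, gamma)
}

#' Local branch weights of the smoothed maximum at one cell
#'
#' The derivatives of the smoothed maximum at cell `(m, l)` with respect to
#' its three arguments: the softmax weights of the diagonal, up and left
#' branch values. They are nonnegative and sum to 1.
#'
#' @param F_tilde Matrix from [diff_nw_forward()].
#' @param P,S_tilde,g,gamma Inputs used to produce `F_tilde`.
#' @param m,l Cell indices, `1 <= m <= M`, `1 <= l <= L`.
#' @return Numeric vector `c(diag, up, left)`.
#' @export
branch_weights <- function(F_tilde, P, S_tilde, g, gamma, m, l) {
  P <- as.matrix(P)
  S_tilde <- as.matrix(S_tilde)
  stopifnot(m >= 1, m <= nrow(P), l >= 1, l <= nrow(S_tilde))
  reward <- sum(P[m, ] * S_tilde[l, ])
  f <- F_tilde[m + 1L, l + 1L]
  w <- c(diag = exp((F_tilde[m, l] + reward - f) / gamma),
         up = exp((F_tilde[m, l + 1L] - g - f) / gamma),
         left = exp((F_tilde[m + 1L, l] - g - f) / gamma))
  w
}

#' Gradient of the span-restricted score w.r.t. the pattern rows
#'
#' Analytic derivative of `F_tilde[M, L]` with respect to each row of the
#' pattern matrix, obtained by one forward fill and one backward sweep that
#' accumulates `dF[M, L] / dF[m, l]` through the three downstream
#' neighbours of every cell. Cost `O(M * L)`.
#'
#' @inheritParams diff_nw_forward
#' @return An `M x 4` matrix of partial derivatives.
#' @export
grad_pattern <- function(P, S_tilde, g, gamma) {
  P <- as.matrix(P)
  S_tilde <- as.matrix(S_tilde)
  if (nrow(S_tilde) == 0L) return(matrix(0, nrow(P), 4L))
  grad_span_cpp(P, S_tilde, g, gamma)$dP
}

#' Gradient of the span-restricted score w.r.t. the gap penalty
#'
#' Forward accumulation of `dF_tilde[m, l] / dg` with boundary seeds `-m`
#' and `-l`; the two gap branches contribute `(child - 1)` and the diagonal
#' branch `child`, each weighted by its softmax branch weight.
#'
#' @inheritParams diff_nw_forward
#' @return A single number, `dF_tilde[M, L] / dg`.
#' @export
grad_gap <- function(P, S_tilde, g, gamma) {
  P <- as.matrix(P)
  S_tilde <- as.matrix(S_tilde)
  if (nrow(S_tilde) == 0L) return(-nrow(P))
  grad_span_cpp(P, S_tilde, g, gamma)$dg
}

#' Backward pass for one training pair
#'
#' Chains the squared-error derivative of the cosine embedding distance
#' against the target alignment distance through the ReLU and the
#' span-restricted differentiable NW into gradients for every parameter.
#' Both Siamese branches share one parameter set, so their contributions
#' are summed. Gradients do not flow through the choice of span itself.
#'
#' @param seq_a,seq_b The two sequences of the pair.
#' @param d_a Target alignment distance in `[0, 1]`.
#' @param params A [pattern_set()].
#' @return A list with `loss`, `de` (predicted embedding distance), and
#'   gradients `dP` (`M x 4 x N` array), `dg` (scalar) and `db` (length-N
#'   vector).
#' @export
loss_backward <- function(seq_a, seq_b, d_a, params) {
  stopifnot(inherits(params, "pattern_set"), d_a >= 0, d_a <= 1)
  S1 <- one_hot_encode(seq_a)
  S2 <- one_hot_encode(seq_b)
  pair_backward_cpp(params$patterns, S1, S2, params$gap, params$bias,
                    params$gamma, d_a)
}

# internal: loss of one pair evaluated through the same span-restricted
# machinery the gradient differentiates (spans frozen at `spans1`/`spans2`).
# Used by the finite-difference oracle so the check isolates the chain rule
# from the span-selection approximation.
span_restricted_pair_loss <- function(S1, S2, spans1, spans2, params, d_a) {
  n <- dim(params$patterns)[3L]
  M <- dim(params$patterns)[1L]
  v_of <- function(S, spans) {
    vapply(seq_len(n), function(k) {
      a <- spans[k, 1L]; z <- spans[k, 2L]
      if (a > z) return(-M * params$gap)
      Ft <- diff_nw_cpp(params$patterns[, , k], S[a:z, , drop = FALSE],
                        params$gap, params$gamma)
      Ft[nrow(Ft), ncol(Ft)]
    }, numeric(1))
  }
  u1 <- pmax(v_of(S1, spans1) + params$bias, 0)
  u2 <- pmax(v_of(S2, spans2) + params$bias, 0)
  de <- cosine_distance(u1, u2)
  (de - d_a)^2
}

#' Finite-difference check of the analytic span gradients
#'
#' Compares [grad_pattern()] and [grad_gap()] against central finite
#' differences of the span-restricted score on random instances, and the
#' full-pair analytic gradient of [loss_backward()] against central finite
#' differences of the span-frozen pair loss on a tiny model. Returns the
#' maximum relative errors observed.
#'
#' @param seed Integer seed.
#' @param trials Number of random instances.
#' @param gamma Smoothing parameter used for the random instances.
#' @param eps Finite-difference step.
#' @return A list with elements `max_rel_pattern`, `max_rel_gap` and
#'   `max_rel_pair`.
#' @export
gradient_check <- function(seed = 7, trials = 100, gamma = 1, eps = 1e-5) {
  set.seed(seed)
  rel_err <- function(a, b) abs(a - b) / pmax(abs(b), 1e-6)
  max_p <- 0
  max_g <- 0
  for (t in seq_len(trials)) {
    M <- sample(2:5, 1L)
    L <- sample(2:8, 1L)
    P <- matrix(stats::rnorm(M * 4), M, 4L)
    St <- one_hot_encode(random_sequence(L))
    g <- stats::runif(1, 0.5, 2)
    dP <- grad_pattern(P, St, g, gamma)
    score <- function(Pm, gv) {
      Ft <- diff_nw_cpp(Pm, St, gv, gamma)
      Ft[nrow(Ft), ncol(Ft)]
    }
    for (i in seq_len(M)) {
      for (j in 1:4) {
        Pp <- P; Pp[i, j] <- Pp[i, j] + eps
        Pm2 <- P; Pm2[i, j] <- Pm2[i, j] - eps
        fd <- (score(Pp, g) - score(Pm2, g)) / (2 * eps)
        max_p <- max(max_p, rel_err(dP[i, j], fd))
      }
    }
    dg <- grad_gap(P, St, g, gamma)
    fd_g <- (score(P, g + eps) - score(P, g - eps)) / (2 * eps)
    max_g <- max(max_g, rel_err(dg, fd_g))
  }

  # end-to-end pair-loss check on a tiny model: finite differences of the
  # span-frozen loss against its analytically composed gradient
  params <- random_pattern_set(2L, 3L, gamma = max(gamma, 0.5), seed = seed + 1L)
  sa <- random_sequence(10L)
  sb <- mutate(sa, mutation_model(sub_rate = 0.2, seed = seed + 2L))
  d_a <- alignment_distance(sa, sb)
  e1 <- embed(sa, params, details = TRUE)
  e2 <- embed(sb, params, details = TRUE)
  S1 <- one_hot_encode(sa)
  S2 <- one_hot_encode(sb)
  an <- span_frozen_pair_grad(S1, S2, e1$spans, e2$spans, params, d_a)
  max_pair <- 0
  for (k in seq_len(2L)) {
    for (i in seq_len(3L)) {
      for (j in 1:4) {
        pp <- params; pp$patterns[i, j, k] <- pp$patterns[i, j, k] + eps
        pm <- params; pm$patterns[i, j, k] <- pm$patterns[i, j, k] - eps
        fd <- (span_restricted_pair_loss(S1, S2, e1$spans, e2$spans, pp, d_a) -
               span_restricted_pair_loss(S1, S2, e1$spans, e2$spans, pm, d_a)) /
              (2 * eps)
        max_pair <- max(max_pair, abs(an$dP[i, j, k] - fd) /
                                  max(abs(fd), 1e-4))
      }
    }
  }
  list(max_rel_pattern = max_p, max_rel_gap = max_g, max_rel_pair = max_pair)
}

# internal: cosine embedding distance plus its gradient w.r.t. both vectors,
# mirroring the compiled implementation (epsilon-guarded norms, zero-norm
# subgradient 0)
cosine_grad <- function(u1, u2) {
  eps <- 1e-8
  n1 <- sqrt(sum(u1^2))
  n2 <- sqrt(sum(u2^2))
  denom <- (n1 + eps) * (n2 + eps)
  dt <- sum(u1 * u2)
  g1 <- -u2 / denom
  g2 <- -u1 / denom
  if (n1 > 0) g1 <- g1 + dt / (n1 * (n1 + eps) * denom) * u1
  if (n2 > 0) g2 <- g2 + dt / (n2 * (n2 + eps) * denom) * u2
  list(de = 1 - dt / denom, g1 = g1, g2 = g2)
}

# internal: exact analytic gradient of span_restricted_pair_loss (spans
# frozen), composed in R from grad_pattern / grad_gap and the cosine chain.
span_frozen_pair_grad <- function(S1, S2, spans1, spans2, params, d_a) {
  n <- dim(params$patterns)[3L]
  M <- dim(params$patterns)[1L]
  v_of <- function(S, spans) {
    vapply(seq_len(n), function(k) {
      a <- spans[k, 1L]; z <- spans[k, 2L]
      if (a > z) return(-M * params$gap)
      Ft <- diff_nw_cpp(params$patterns[, , k], S[a:z, , drop = FALSE],
                        params$gap, params$gamma)
      Ft[nrow(Ft), ncol(Ft)]
    }, numeric(1))
  }
  v1 <- v_of(S1, spans1)
  v2 <- v_of(S2, spans2)
  u1 <- pmax(v1 + params$bias, 0)
  u2 <- pmax(v2 + params$bias, 0)
  cg <- cosine_grad(u1, u2)
  dde <- 2 * (cg$de - d_a)
  gu1 <- dde * cg$g1
  gu2 <- dde * cg$g2
  dP <- array(0, dim(params$patterns))
  db <- numeric(n)
  dg <- 0
  for (k in seq_len(n)) {
    for (side in 1:2) {
      S <- if (side == 1L) S1 else S2
      v <- if (side == 1L) v1 else v2
      gu <- if (side == 1L) gu1 else gu2
      spans <- if (side == 1L) spans1 else spans2
      if (v[k] + params$bias[k] <= 0) next
      db[k] <- db[k] + gu[k]
      a <- spans[k, 1L]; z <- spans[k, 2L]
      if (a > z) {
        dg <- dg + gu[k] * (-M)
        next
      }
      St <- S[a:z, , drop = FALSE]
      dP[, , k] <- dP[, , k] +
        gu[k] * grad_pattern(params$patterns[, , k], St, params$gap,
                             params$gamma)
      dg <- dg + gu[k] * grad_gap(params$patterns[, , k], St, params$gap,
                                  params$gamma)
    }
  }
  list(loss = (cg$de - d_a)^2, de = cg$de, dP = dP, dg = dg, db = db)
}
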