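#' Cosine distance between two embeddings
#'
#' `1 - (u1 . u2) / ((|u1| + eps) * (|u2| + eps))` with `eps = 1e-8`.
#' Symmetric; for nonnegative embeddings the value lies in `[0, 1]` (up to
#' epsilon slack). Two zero vectors are at distance 1 by convention.
#'
#' @param u1,u2 Numeric vectors of equal length.
#' @return A single number.
#' @export
cosine_distance <- function(u1, u2) {
  stopifnot(length(u1) == length(u2), length(u1) >= 1L)
  cosine_distance_cpp(as.numeric(u1), as.numeric(u2))
}

#' Training configuration
#'
#' Hyperparameters of the Siamese training loop. The defaults (300 patterns
#' of length 20, learning rate 1e-4, 200 epochs, Adam) are the recommended
#' full-scale setting; desk-scale runs typically use fewer, shorter
#' patterns and fewer epochs.
#'
#' @param n_patterns Number of patterns `N`.
#' @param pattern_len Pattern length `M`.
#' @param gamma Smoothing parameter of the soft maximum.
#' @param learning_rate Adam learning rate.
#' @param epochs Number of passes over the training pairs.
#' @param batch_size Mini-batch size (pairs per gradient step).
#' @param seed Master seed driving initialization and shuffling.
#' @return An object of class `train_config`.
#' @export
train_config <- function(n_patterns = 300L, pattern_len = 20L, gamma = 0.1,
                         learning_rate = 1e-4, epochs = 200L,
                         batch_size = 32L, seed = 1L) {
  stopifnot(n_patterns >= 1, pattern_len >= 1, gamma > 0,
            learning_rate >= 0, epochs >= 1, batch_size >= 1)
  structure(list(n_patterns = as.integer(n_patterns),
                 pattern_len = as.integer(pattern_len),
                 gamma = gamma, learning_rate = learning_rate,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed), optimizer = "adam"),
            class = "train_config")
}

#' Sample training pairs with alignment-distance targets
#'
#' Draws `n_pairs` sequence pairs uniformly with replacement (self-pairs
#' excluded, duplicate pairs allowed) and computes the target alignment
#' distance of each with the affine-gap NW machinery.
#'
#' @param seqs Sequences (character vector or [Biostrings::DNAStringSet]);
#'   at least 2.
#' @param n_pairs Number of pairs to draw.
#' @param scoring An [nw_scoring()] object.
#' @param seed Integer seed.
#' @return A data frame with columns `seq_a`, `seq_b` (residue strings) and
#'   `d_a` (alignment distance in `[0, 1]`).
#' @export
make_training_pairs <- function(seqs, n_pairs, scoring = nw_scoring(),
                                seed = 1L) {
  chars <- as_seq_chars(seqs)
  n <- length(chars)
  stopifnot(n >= 2L, n_pairs >= 1L)
  set.seed(seed)
  ia <- sample.int(n, n_pairs, replace = TRUE)
  ib <- sample.int(n - 1L, n_pairs, replace = TRUE)
  ib <- ifelse(ib >= ia, ib + 1L, ib)  # uniform over pairs with ib != ia
  d <- alignment_distances(chars, cbind(ia, ib), scoring)
  data.frame(seq_a = unname(chars[ia]), seq_b = unname(chars[ib]),
             d_a = d$distance, stringsAsFactors = FALSE)
}

#' Mean squared error of a pattern set on training pairs
#'
#' Mean over pairs of the squared difference between the cosine embedding
#' distance and the target alignment distance.
#'
#' @param pairs Data frame with columns `seq_a`, `seq_b`, `d_a`
#'   (see [make_training_pairs()]).
#' @param params A [pattern_set()].
#' @return A nonnegative number; 0 iff all predictions are exact.
#' @export
mse_loss <- function(pairs, params) {
  stopifnot(nrow(pairs) >= 1L)
  de <- predicted_distances(pairs, params)
  mean((de - pairs$d_a)^2)
}

#' Predicted embedding distances for pairs
#'
#' Embeds every distinct sequence in `pairs` once, then returns the cosine
#' distance per pair.
#'
#' @inheritParams mse_loss
#' @return Numeric vector of length `nrow(pairs)`.
#' @export
predicted_distances <- function(pairs, params) {
  uniq <- unique(c(pairs$seq_a, pairs$seq_b))
  emb <- embed_sequences(stats::setNames(uniq, uniq), params)
  ia <- match(pairs$seq_a, uniq)
  ib <- match(pairs$seq_b, uniq)
  vapply(seq_len(nrow(pairs)),
         function(k) cosine_distance(emb[ia[k], ], emb[ib[k], ]),
         numeric(1))
}

#' Train the Siamese soft-ASM embedding network
#'
#' Minimizes the mean squared error between cosine embedding distances and
#' alignment distances by Adam over shuffled mini-batches. Both Siamese
#' branches share a single parameter set updated with summed gradients.
#' Patterns are initialized i.i.d. uniform(0, 1), the gap penalty at 1 and
#' the bias at 0, all from the configured seed, so runs are fully
#' reproducible. The gap penalty is floor-clamped at 1e-3 after every step
#' to stay positive.
#'
#' @param pairs Data frame with columns `seq_a`, `seq_b`, `d_a`.
#' @param config A [train_config()].
#' @param init Initialization scheme. `"subsequence"` (default) seeds each
#'   pattern with the one-hot encoding of a random length-`M` subsequence of
#'   the training data and centers each unit's pre-activation at zero
#'   (`b_n = -median(v_n)` over the training sequences), so units start
#'   selective and embedding distances span their full range.
#'   `"uniform"` draws pattern entries i.i.d. uniform(0, 1) with zero bias.
#'   Either way the gap penalty starts at 1. Alternatively a
#'   [pattern_set()] to start from.
#' @param verbose If TRUE, log per-epoch loss to stderr.
#' @return A list of class `asmatch_fit` with `params` (the trained
#'   [pattern_set()]) and `loss` (data frame with per-epoch mean training
#'   loss).
#' @export
train_asmatch <- function(pairs, config = train_config(),
                        init = c("subsequence", "uniform"), verbose = FALSE) {
  stopifnot(inherits(config, "train_config"),
            nrow(pairs) >= config$batch_size)
  set.seed(config$seed)
  if (inherits(init, "pattern_set")) {
    params <- init
    stopifnot(dim(params$patterns)[1L] == config$pattern_len,
              dim(params$patterns)[3L] == config$n_patterns)
  } else {
    init <- match.arg(init)
    params <- init_pattern_set(pairs, config, init)
  }
  uniq <- unique(c(pairs$seq_a, pairs$seq_b))
  Slist <- lapply(uniq, one_hot_encode)
  ia <- match(pairs$seq_a, uniq)
  ib <- match(pairs$seq_b, uniq)
  npairs <- nrow(pairs)

  # Adam state for patterns, gap, bias
  dims <- dim(params$patterns)
  mP <- array(0, dims); vP <- array(0, dims)
  mg <- 0; vg <- 0
  mb <- numeric(dims[3L]); vb <- numeric(dims[3L])
  b1 <- 0.9; b2 <- 0.999; adam_eps <- 1e-8
  lr <- config$learning_rate
  step <- 0L
  history <- numeric(config$epochs)

  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(npairs)
    epoch_loss <- 0
    nb <- 0L
    for (start in seq(1L, npairs, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, npairs)]
      gP <- array(0, dims); gg <- 0; gb <- numeric(dims[3L])
      batch_loss <- 0
      for (k in idx) {
        bw <- pair_backward_cpp(params$patterns, Slist[[ia[k]]],
                                Slist[[ib[k]]], params$gap, params$bias,
                                params$gamma, pairs$d_a[k])
        gP <- gP + bw$dP
        gg <- gg + bw$dg
        gb <- gb + bw$db
        batch_loss <- batch_loss + bw$loss
      }
      nk <- length(idx)
      gP <- gP / nk; gg <- gg / nk; gb <- gb / nk
      batch_loss <- batch_loss / nk
      if (!is.finite(batch_loss))
        stop("non-finite loss in epoch ", epoch, ", batch starting at pair ",
             start)
      step <- step + 1L
      corr1 <- 1 - b1^step
      corr2 <- 1 - b2^step
      mP <- b1 * mP + (1 - b1) * gP
      vP <- b2 * vP + (1 - b2) * gP^2
      params$patterns <- params$patterns -
        lr * (mP / corr1) / (sqrt(vP / corr2) + adam_eps)
      mg <- b1 * mg + (1 - b1) * gg
      vg <- b2 * vg + (1 - b2) * gg^2
      params$gap <- max(params$gap -
                          lr * (mg / corr1) / (sqrt(vg / corr2) + adam_eps),
                        1e-3)
      mb <- b1 * mb + (1 - b1) * gb
      vb <- b2 * vb + (1 - b2) * gb^2
      params$bias <- params$bias -
        lr * (mb / corr1) / (sqrt(vb / corr2) + adam_eps)
      epoch_loss <- epoch_loss + batch_loss
      nb <- nb + 1L
    }
    history[epoch] <- epoch_loss / nb
    if (verbose)
      message(sprintf("epoch %d/%d  loss %.6f", epoch, config$epochs,
                      history[epoch]))
  }
  structure(list(params = params,
                 loss = data.frame(epoch = seq_len(config$epochs),
                                   loss = history),
                 config = config),
            class = "asmatch_fit")
}

#' @export
print.asmatch_fit <- function(x, ...) {
  cat(sprintf("asmatch_fit: %d epochs, final training loss %.6f\n",
              nrow(x$loss), x$loss$loss[nrow(x$loss)]))
  print(x$params)
  invisible(x)
}

# internal: build the initial pattern set for train_asmatch (RNG already
# seeded by the caller)
init_pattern_set <- function(pairs, config, scheme) {
  if (scheme == "uniform")
    return(random_pattern_set(config$n_patterns, config$pattern_len,
                              gamma = config$gamma))
  M <- config$pattern_len
  uniq <- unique(c(pairs$seq_a, pairs$seq_b))
  long <- uniq[nchar(uniq) >= M]
  if (length(long) == 0L)
    stop("no training sequence is as long as pattern_len; ",
         "use init = \"uniform\"")
  pat <- array(0, c(M, 4L, config$n_patterns))
  for (n in seq_len(config$n_patterns)) {
    s <- long[sample.int(length(long), 1L)]
    st <- sample.int(nchar(s) - M + 1L, 1L)
    pat[, , n] <- one_hot_encode(substr(s, st, st + M - 1L))
  }
  params <- pattern_set(pat, gap = 1, gamma = config$gamma)
  # center each unit's pre-activation at its median over (a sample of) the
  # training sequences, so roughly half the units fire per sequence
  ref <- uniq
  if (length(ref) > 200L) ref <- ref[sample.int(length(ref), 200L)]
  V <- embed_sequences(ref, params)  # bias is 0 here, so u = max(v, 0) = v
  params$bias <- -apply(V, 2L, stats::median)
  params
}

# container format version written by save_model
MODEL_FORMAT_VERSION <- 1L

#' Save / load a trained pattern set
#'
#' The container embeds the format version, alphabet column order and all
#' hyperparameters, and round-trips bit-exactly. Loading a file with an
#' unknown format version is an explicit error, never a silent coercion.
#'
#' @param params A [pattern_set()] (an `asmatch_fit` is also accepted; its
#'   `$params` is saved).
#' @param path File path for the model container.
#' @return `save_model`: `path` invisibly. `load_model`: a [pattern_set()].
#' @export
save_model <- function(params, path) {
  if (inherits(params, "asmatch_fit")) params <- params$params
  stopifnot(inherits(params, "pattern_set"))
  saveRDS(params, path, version = 3L)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  obj <- tryCatch(readRDS(path),
                  error = function(e) stop("cannot read model file ", path,
                                           ": ", conditionMessage(e)))
  if (!inherits(obj, "pattern_set"))
    stop("not a pattern-set model container: ", path)
  if (is.null(obj$format_version) ||
      obj$format_version != MODEL_FORMAT_VERSION)
    stop("unsupported model format version in ", path)
  obj
}
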