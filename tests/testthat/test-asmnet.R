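test_that("soft_max_gamma matches its closed form and limits", {
  expect_equal(soft_max_gamma(c(0, 0, 0), 1), log(3))
  expect_equal(soft_max_gamma(c(5, -1000, -1000), 0.1), 5, tolerance = 1e-12)
  expect_equal(soft_max_gamma(c(1, 0, -1), 1),
               1 + log(1 + exp(-1) + exp(-2)))
  # stability at extreme magnitudes
  expect_equal(soft_max_gamma(c(1e8, 1e8 - 5), 0.5), 1e8, tolerance = 1e-7)
  expect_equal(soft_max_gamma(c(-1e8, -1e8), 1), -1e8 + log(2))
})

test_that("soft_max_gamma is sandwiched between max and max + gamma*log(J)", {
  set.seed(2)
  for (i in 1:50) {
    a <- rnorm(sample(1:6, 1), sd = 10)
    g <- runif(1, 0.01, 2)
    v <- soft_max_gamma(a, g)
    expect_gte(v, max(a))
    expect_lte(v, max(a) + g * log(length(a)) + 1e-12)
  }
})

test_that("soft_asm_forward boundary conditions hold for any input", {
  set.seed(4)
  P <- matrix(rnorm(5 * 4), 5, 4)
  S <- one_hot_encode(random_dna(12))
  f <- soft_asm_forward(P, S, g = 1.3, gamma = 0.2)
  expect_equal(f$F[1, ], rep(0, 13))
  expect_equal(f$F[, 1], -(0:5) * 1.3)
})

test_that("an exactly matching one-hot pattern scores about M", {
  s <- "TTACGTACGGTT"
  sub <- substr(s, 3, 8)
  P <- onehot_pattern(sub)
  f <- soft_asm_forward(P, one_hot_encode(s), g = 1, gamma = 1e-3)
  expect_equal(f$v, nchar(sub), tolerance = 1e-2)
  expect_equal(best_match_span(f, 1, 1e-3, P, one_hot_encode(s)),
               c(3L, 8L))
})

test_that("soft score decreases with gamma and converges to the hard max", {
  set.seed(9)
  for (i in 1:20) {
    M <- sample(2:6, 1)
    P <- matrix(rnorm(M * 4), M, 4)
    S <- one_hot_encode(random_dna(sample(4:15, 1)))
    g <- runif(1, 0.5, 2)
    hard <- hard_max_asm_score(P, S, g)
    gammas <- c(1, 0.3, 0.1, 1e-2, 1e-4)
    vs <- vapply(gammas, function(gg) soft_asm_forward(P, S, g, gg)$v,
                 numeric(1))
    expect_true(all(diff(vs) <= 1e-12))
    expect_gte(min(vs) + 1e-12, hard)
    expect_equal(vs[length(vs)], hard, tolerance = 5e-3)
  }
})

test_that("per-cell sandwich bound: hard recursion <= soft <= hard + slack", {
  # the soft recursion adds at most gamma * log(3) of slack per cell
  set.seed(13)
  for (i in 1:10) {
    M <- sample(2:5, 1)
    L <- sample(3:10, 1)
    P <- matrix(rnorm(M * 4), M, 4)
    S <- one_hot_encode(random_dna(L))
    g <- runif(1, 0.5, 2)
    gamma <- runif(1, 0.05, 1)
    f <- soft_asm_forward(P, S, g, gamma)
    # hard recursion, cell by cell
    R <- P %*% t(S)
    H <- matrix(0, M + 1, L + 1)
    H[, 1] <- -(0:M) * g
    H[1, ] <- 0
    for (l in 1:L) for (m in 1:M)
      H[m + 1, l + 1] <- max(H[m, l] + R[m, l], H[m, l + 1] - g,
                             H[m + 1, l] - g)
    expect_true(all(f$F - H >= -1e-9))
    expect_true(all(f$F - H <= gamma * (row(H) + col(H) - 2) * log(3) + 1e-9))
  }
})

test_that("hard_max_asm_score agrees with brute force over windows", {
  # brute force: best global alignment score of the pattern against any
  # contiguous window, rewards p_m . s_l, gaps -g
  window_brute <- function(P, s_chars, g) {
    M <- nrow(P)
    S <- one_hot_encode(paste(s_chars, collapse = ""))
    L <- length(s_chars)
    global_score <- function(cols) {
      Lw <- length(cols)
      F <- matrix(-Inf, M + 1, Lw + 1)
      F[1, ] <- -(0:Lw) * g
      F[, 1] <- -(0:M) * g
      for (m in 1:M) for (l in seq_len(Lw))
        F[m + 1, l + 1] <- max(F[m, l] + sum(P[m, ] * S[cols[l], ]),
                               F[m, l + 1] - g, F[m + 1, l] - g)
      F[M + 1, Lw + 1]
    }
    best <- -M * g  # empty window
    for (a in 1:L) for (z in a:L)
      best <- max(best, global_score(a:z))
    best
  }
  set.seed(17)
  for (i in 1:25) {
    M <- sample(2:5, 1)
    L <- sample(3:10, 1)
    P <- matrix(rnorm(M * 4), M, 4)
    s <- random_dna(L)
    g <- runif(1, 0.5, 2)
    expect_equal(hard_max_asm_score(P, one_hot_encode(s), g),
                 window_brute(P, strsplit(s, "")[[1]], g),
                 tolerance = 1e-10)
  }
})

test_that("hard_max_asm_score boundary convention: empty pattern scores 0", {
  expect_equal(hard_max_asm_score(matrix(0, 0, 4), one_hot_encode("ACGT"), 1),
               0)
})

test_that("soft and hard backtracked spans agree on most instances", {
  # hard-max reference: same reward recursion with the exact max, same tie
  # order (last-row ties to the smallest column, branches diag > up > left)
  hard_span <- function(P, S, g) {
    M <- nrow(P)
    L <- nrow(S)
    R <- P %*% t(S)
    F <- matrix(0, M + 1, L + 1)
    F[, 1] <- -(0:M) * g
    F[1, ] <- 0
    for (l in 1:L) for (m in 1:M)
      F[m + 1, l + 1] <- max(F[m, l] + R[m, l], F[m, l + 1] - g,
                             F[m + 1, l] - g)
    l <- which.max(F[M + 1, ]) - 1L
    lstar <- l
    m <- M
    while (m > 0) {
      if (l == 0) { m <- m - 1; next }
      br <- c(F[m, l] + R[m, l], F[m, l + 1] - g, F[m + 1, l] - g)
      k <- which.max(br)
      if (k == 1) { m <- m - 1; l <- l - 1 }
      else if (k == 2) m <- m - 1
      else l <- l - 1
    }
    c(l + 1L, lstar)
  }
  set.seed(21)
  agree <- 0
  trials <- 200
  for (i in 1:trials) {
    M <- sample(2:6, 1)
    P <- matrix(rnorm(M * 4), M, 4)
    s <- random_dna(sample(5:15, 1))
    S <- one_hot_encode(s)
    f <- soft_asm_forward(P, S, g = 1, gamma = 1e-3)
    soft_span <- best_match_span(f, 1, 1e-3, P, S)
    if (all(soft_span == hard_span(P, S, 1))) agree <- agree + 1
  }
  expect_gte(agree / trials, 0.95)
})

test_that("soft scores have the column-wise prefix property", {
  # appending a suffix leaves the F entries over shared columns unchanged
  set.seed(25)
  P <- matrix(rnorm(4 * 4), 4, 4)
  s <- random_dna(10)
  f1 <- soft_asm_forward(P, one_hot_encode(s), 1, 0.2)
  f2 <- soft_asm_forward(P, one_hot_encode(paste0(s, random_dna(5))), 1, 0.2)
  expect_equal(f2$F[, 1:11], f1$F)
})

test_that("embeddings are nonnegative, N-dimensional and deterministic", {
  set.seed(29)
  params <- random_pattern_set(6, 4, gamma = 0.1)
  for (len in c(5, 20, 61)) {
    u <- embed(random_dna(len), params)
    expect_length(u, 6)
    expect_true(all(u >= 0))
  }
  s <- random_dna(30)
  expect_identical(embed(s, params), embed(s, params))

  # strongly negative bias clips everything to zero
  params$bias <- rep(-1e6, 6)
  expect_equal(embed(s, params), rep(0, 6))
})

test_that("a single exactly matching pattern embeds to about M", {
  s <- "TTACGTACGGTT"
  P <- onehot_pattern(substr(s, 3, 10))
  params <- pattern_set(P, gap = 1, bias = 0, gamma = 1e-3)
  expect_equal(embed(s, params), 8, tolerance = 1e-2)
})

test_that("embed_sequences stacks per-sequence embeddings", {
  set.seed(33)
  params <- random_pattern_set(5, 3, gamma = 0.1)
  seqs <- c(a = random_dna(12), b = random_dna(30))
  m <- embed_sequences(seqs, params)
  expect_equal(dim(m), c(2L, 5L))
  expect_equal(rownames(m), c("a", "b"))
  expect_equal(m[1, ], embed(seqs[["a"]], params))
  expect_equal(m[2, ], embed(seqs[["b"]], params))
})
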