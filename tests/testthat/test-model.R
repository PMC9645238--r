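test_that("cosine_distance handles identity, orthogonality and zeros", {
  set.seed(1)
  u <- runif(10)
  expect_equal(cosine_distance(u, u), 0, tolerance = 1e-6)
  expect_equal(cosine_distance(c(1, 0), c(0, 1)), 1)
  expect_equal(cosine_distance(c(0, 0), c(1, 1)), 1)
  expect_equal(cosine_distance(c(0, 0), c(0, 0)), 1)
  # symmetry
  v <- runif(10)
  expect_identical(cosine_distance(u, v), cosine_distance(v, u))
})

test_that("mse_loss is the mean squared prediction error", {
  set.seed(5)
  params <- random_pattern_set(4, 3, gamma = 0.1)
  a <- random_dna(15)
  b <- random_dna(15)
  de <- cosine_distance(embed(a, params), embed(b, params))
  pairs <- data.frame(seq_a = a, seq_b = b, d_a = de)
  expect_equal(mse_loss(pairs, params), 0, tolerance = 1e-15)

  pairs2 <- data.frame(seq_a = a, seq_b = b, d_a = de + 0.2)
  expect_equal(mse_loss(pairs2, params), 0.04, tolerance = 1e-10)

  # permutation invariance
  pairs3 <- rbind(pairs, pairs2)
  expect_equal(mse_loss(pairs3, params), mse_loss(pairs3[2:1, ], params))
})

test_that("make_training_pairs excludes self-pairs and hits its targets", {
  set.seed(9)
  seqs <- setNames(vapply(1:8, function(i) random_dna(30), character(1)),
                   paste0("s", 1:8))
  pairs <- make_training_pairs(seqs, 200, seed = 3)
  expect_equal(nrow(pairs), 200)
  expect_true(all(pairs$seq_a != pairs$seq_b))
  expect_true(all(pairs$d_a >= 0 & pairs$d_a <= 1))
  # targets match the alignment module
  k <- sample(200, 5)
  for (i in k)
    expect_equal(pairs$d_a[i],
                 alignment_distance(pairs$seq_a[i], pairs$seq_b[i]))
  # determinism
  expect_identical(pairs, make_training_pairs(seqs, 200, seed = 3))
})

test_that("siamese prediction is symmetric in the pair order", {
  set.seed(13)
  params <- random_pattern_set(5, 4, gamma = 0.1)
  a <- random_dna(25)
  b <- random_dna(25)
  expect_identical(cosine_distance(embed(a, params), embed(b, params)),
                   cosine_distance(embed(b, params), embed(a, params)))
})

test_that("training is reproducible and inert at lr = 0", {
  set.seed(17)
  seqs <- vapply(1:10, function(i) random_dna(40), character(1))
  pairs <- make_training_pairs(seqs, 40, seed = 5)
  cfg <- train_config(n_patterns = 3, pattern_len = 4, gamma = 0.1,
                      learning_rate = 1e-3, epochs = 5, batch_size = 8,
                      seed = 11)
  f1 <- train_asmatch(pairs, cfg)
  f2 <- train_asmatch(pairs, cfg)
  expect_identical(f1$loss, f2$loss)
  expect_identical(f1$params, f2$params)

  cfg0 <- train_config(n_patterns = 3, pattern_len = 4, gamma = 0.1,
                       learning_rate = 0, epochs = 3, batch_size = 8,
                       seed = 11)
  f0 <- train_asmatch(pairs, cfg0)
  init <- train_asmatch(pairs, train_config(n_patterns = 3, pattern_len = 4,
                                          gamma = 0.1, learning_rate = 0,
                                          epochs = 1, batch_size = 8,
                                          seed = 11))
  expect_equal(f0$params, init$params)
  expect_equal(var(f0$loss$loss), 0)
})

test_that("200 Adam steps cut the loss by at least half on a tiny problem", {
  set.seed(21)
  fam <- make_families(4, 10, 60, seed = 3)
  seqs <- fam$records$seq
  pairs <- make_training_pairs(seqs, 20, seed = 3)
  # batch = 1 pair for 10 epochs over 20 pairs = 200 gradient steps
  cfg <- train_config(n_patterns = 4, pattern_len = 4, gamma = 0.1,
                      learning_rate = 1e-2, epochs = 10, batch_size = 1,
                      seed = 3)
  fit <- train_asmatch(pairs, cfg)
  expect_lt(fit$loss$loss[10], 0.5 * fit$loss$loss[1])
})

test_that("model save / load round-trips bit-exactly", {
  set.seed(25)
  params <- random_pattern_set(4, 8, gamma = 0.07)
  params$bias <- rnorm(4)
  tf <- tempfile(fileext = ".asmatch")
  save_model(params, tf)
  back <- load_model(tf)
  expect_identical(back, params)
  expect_equal(dim(back$patterns)[1], 8)  # M preserved

  # truncated file fails loudly
  raw <- readBin(tf, "raw", file.size(tf))
  tf2 <- tempfile()
  writeBin(raw[1:20], tf2)
  expect_error(load_model(tf2), "cannot read model file")

  # foreign or version-mismatched containers are rejected
  tf3 <- tempfile()
  saveRDS(list(a = 1), tf3)
  expect_error(load_model(tf3), "not a pattern-set")
  bad <- params
  bad$format_version <- 99L
  tf4 <- tempfile()
  saveRDS(bad, tf4)
  expect_error(load_model(tf4), "format version")
})
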