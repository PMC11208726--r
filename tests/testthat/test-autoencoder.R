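
test_that("layer widths reproduce hand-computed profiles", {
  for (case in WIDTH_CASES) {
    dims <- case[[1]]
    spec <- architecture_spec(dims[1], hl = dims[2], bn = dims[3],
                              shape = case[[2]])
    expect_equal(layer_widths(spec), as.integer(case[[3]]),
                 label = paste(dims, collapse = "/"))
  }
})

test_that("width profiles are symmetric, boundary-exact and tapered", {
  set.seed(51)
  for (rep in 1:25) {
    input_dim <- sample(2:120, 1)
    hl <- sample(1:6, 1)
    bn <- sample(seq_len(input_dim), 1)
    shape <- sample(c("elliptic", "rectangular"), 1)
    w <- layer_widths(architecture_spec(input_dim, hl, bn, shape))
    expect_length(w, 2 * hl + 3)
    expect_equal(w, rev(w))
    expect_equal(w[1], input_dim)
    expect_equal(w[hl + 2], bn)
    enc <- w[1:(hl + 2)]
    expect_true(all(diff(enc) <= 0))  # non-increasing to the bottleneck
  }
  expect_error(architecture_spec(5, 2, 6), "exceed")
})

test_that("output activation is the shifted tanh with open range (0, 2)", {
  expect_equal(output_activation(0), 1)
  expect_equal(output_activation(1), tanh(1) + 1)
  expect_equal(output_activation(1), 1.7616, tolerance = 1e-4)
  x <- seq(-15, 15, length.out = 301)
  y <- output_activation(x)
  expect_true(all(y > 0 & y < 2))
  expect_true(all(diff(y) >= 0))
  expect_equal(output_activation(x) + output_activation(-x), rep(2, 301))
})

test_that("built models have the advertised layer count and parameter count", {
  spec <- architecture_spec(4, hl = 1, bn = 2)
  net <- build_autoencoder(spec)
  expect_equal(layer_widths(spec), c(4, 3, 2, 3, 4))
  n_par <- sum(vapply(seq_along(net$W),
                      function(k) length(net$W[[k]]) + length(net$b[[k]]),
                      numeric(1)))
  expect_equal(n_par, (4 * 3 + 3) + (3 * 2 + 2) + (2 * 3 + 3) + (3 * 4 + 4))
  expect_length(layer_widths(architecture_spec(10, hl = 4, bn = 3)), 11)
})

test_that("identical seeds give identical initial weights; He-uniform bounds hold", {
  spec <- architecture_spec(12, hl = 2, bn = 3)
  n1 <- build_autoencoder(spec, train_recipe(seed = 99))
  n2 <- build_autoencoder(spec, train_recipe(seed = 99))
  expect_identical(n1$W, n2$W)
  n3 <- build_autoencoder(spec, train_recipe(seed = 100))
  expect_false(identical(n1$W, n3$W))
  for (k in seq_along(n1$W)) {
    lim <- sqrt(6 / nrow(n1$W[[k]]))
    expect_true(all(abs(n1$W[[k]]) <= lim))
    expect_equal(n1$b[[k]], rep(0, ncol(n1$W[[k]])))
  }
})

test_that("reconstructions stay in (0,2) and rounded values in {0,1,2}", {
  d <- fixture_block(8, K = 3, eps = 0.01, n = 200, seed = 52)
  fit <- train_block(architecture_spec(8, hl = 2, bn = 2), d,
                     recipe = train_recipe(epochs = 3), block_id = "rng")
  out <- reconstruct(fit, d)
  expect_true(all(out > 0 & out < 2))
  rounded <- pmin(pmax(floor(out + 0.5), 0), 2)
  expect_true(all(rounded %in% 0:2))
})

test_that("snp_accuracy rounds half-up and decomposes by dosage", {
  truth <- matrix(c(0, 1, 2, 0, 1, 2), 2, 3)
  expect_equal(snp_accuracy(truth, truth)$overall, 1)
  # predictions all ~1 against balanced truth: only the 1s match
  pred1 <- matrix(1.0, 2, 3)
  expect_equal(snp_accuracy(pred1, truth)$overall, 1 / 3)
  # rounding boundary: 1.49 -> 1 correct, 1.51 -> 2 wrong
  expect_equal(snp_accuracy(matrix(1.49), matrix(1))$overall, 1)
  expect_equal(snp_accuracy(matrix(1.51), matrix(1))$overall, 0)
  expect_equal(snp_accuracy(matrix(0.5), matrix(1))$overall, 1)  # half up
  # per-dosage accuracies recombine exactly to the overall value
  set.seed(53)
  truth2 <- matrix(sample(0:2, 60, TRUE), 6, 10)
  pred2 <- truth2 + matrix(rnorm(60, sd = 0.6), 6, 10)
  pred2 <- pmin(pmax(pred2, 1e-6), 2 - 1e-6)
  m <- snp_accuracy(pred2, truth2)
  pooled <- sum(m$by_dosage * m$n_by_dosage, na.rm = TRUE) / sum(m$n_by_dosage)
  expect_equal(m$overall, pooled)
  expect_error(snp_accuracy(matrix(1), matrix(1, 2, 2)), "shape")
})

test_that("snp_accuracy is invariant under sample permutation", {
  set.seed(54)
  truth <- matrix(sample(0:2, 80, TRUE), 8, 10)
  pred <- pmin(pmax(truth + rnorm(80, sd = 0.4), 0.001), 1.999)
  perm <- sample(8)
  expect_equal(snp_accuracy(pred[perm, ], truth[perm, ])$overall,
               snp_accuracy(pred, truth)$overall)
})

test_that("compression ratio is bn over input dimension", {
  expect_equal(compression_ratio(3, 30), 0.10)
  expect_equal(compression_ratio(1, 1), 1.0)
  expect_equal(round(100 * compression_ratio(7341, 70247), 2), 10.45)
  expect_error(compression_ratio(3, 0), "positive")
  expect_error(compression_ratio(5, 4), "bn")
})

test_that("a constant block is reconstructed perfectly", {
  d <- matrix(rep(c(0L, 1L, 2L, 0L, 1L), each = 150), 150, 5)
  fit <- train_block(architecture_spec(5, hl = 2, bn = 1), d,
                     recipe = train_recipe(epochs = 100, learning_rate = 1e-2),
                     block_id = "const")
  expect_equal(fit$val_acc, 1)
})

test_that("a two-founder noiseless block separates through one latent dimension", {
  d <- fixture_block(10, K = 2, eps = 0, n = 600, seed = 55)
  fit <- train_block(architecture_spec(10, hl = 4, bn = 1), d,
                     recipe = train_recipe(epochs = 50, learning_rate = 1e-3),
                     block_id = "k2bn1")
  expect_gte(fit$val_acc, 0.99)
})

test_that("training reduces the loss between first and final epoch", {
  d <- fixture_block(8, K = 3, eps = 0.005, n = 300, seed = 56)
  fit <- train_block(architecture_spec(8, hl = 2, bn = 2), d,
                     recipe = train_recipe(epochs = 10), block_id = "mono")
  expect_lt(fit$history[length(fit$history)], fit$history[1])
})

test_that("training is reproducible for a fixed seed and data", {
  d <- fixture_block(6, K = 2, eps = 0.01, n = 200, seed = 57)
  r <- train_recipe(epochs = 5, seed = 7)
  f1 <- train_block(architecture_spec(6, hl = 2, bn = 2), d, recipe = r,
                    block_id = "rep")
  f2 <- train_block(architecture_spec(6, hl = 2, bn = 2), d, recipe = r,
                    block_id = "rep")
  expect_identical(f1$val_mse, f2$val_mse)
  expect_identical(f1$val_acc, f2$val_acc)
  expect_identical(f1$net$W, f2$net$W)
})

test_that("encode returns bottleneck-wide embeddings, equal for equal rows", {
  d <- fixture_block(9, K = 4, eps = 0, n = 300, seed = 58)
  fit <- train_block(architecture_spec(9, hl = 2, bn = 3), d,
                     recipe = train_recipe(epochs = 5), block_id = "emb")
  emb <- encode(fit, d)
  expect_equal(ncol(emb), 3)
  expect_equal(nrow(emb), nrow(d))
  same <- which(duplicated(d) | duplicated(d, fromLast = TRUE))
  if (length(same) >= 2) {
    i <- same[1]
    j <- setdiff(which(apply(d, 1, identical, d[i, ])), i)[1]
    expect_equal(emb[i, ], emb[j, ])
  }
  # distinct embeddings bounded by distinct founder genotype combinations
  expect_lte(nrow(unique(round(emb, 8))), 4 * 5 / 2)
  expect_error(encode(fit, d[, 1:5]), "columns")
})

test_that("widening the bottleneck does not hurt attainable accuracy", {
  d <- fixture_block(10, K = 4, eps = 0.005, n = 600, seed = 59)
  r <- train_recipe(epochs = 100, learning_rate = 1e-3)
  accs <- vapply(c(1, 3, 6), function(bn) {
    train_block(architecture_spec(10, hl = 2, bn = bn), d, recipe = r,
                block_id = paste0("bn", bn))$val_acc
  }, numeric(1))
  expect_gte(accs[2], accs[1] - 0.02)
  expect_gte(accs[3], accs[2] - 0.02)
})
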