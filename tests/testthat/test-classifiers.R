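test_that("the 70/15/15 split is exhaustive, disjoint, stratified, seeded", {
  y <- rep(c("HC", "OA"), each = 50)
  sp <- split_dataset(y, seed = 3)
  expect_equal(lengths(sp), c(train = 70L, test = 15L, validation = 15L))
  all_idx <- sort(c(sp$train, sp$test, sp$validation))
  expect_equal(all_idx, 1:100)
  expect_identical(split_dataset(y, seed = 3), sp)
  expect_false(identical(split_dataset(y, seed = 4), sp))
  # every split keeps both classes under stratification
  for (s in sp) expect_setequal(unique(y[s]), c("HC", "OA"))
  expect_error(split_dataset(rep("HC", 5)), "at least 10")
  expect_error(split_dataset(c(rep("HC", 18), rep("OA", 2)),
                             fractions = c(train = 0.1, test = 0.45,
                                           validation = 0.45)),
               "empty")
})

test_that("network specs enforce the family conventions", {
  expect_error(network_spec("RBF", 4, 8, hidden_activation = "tanh"), "Gauss")
  expect_error(network_spec("MLP", 4, 8, output_activation = "linear",
                            error_function = "entropy"), "softmax")
  expect_error(network_spec("MLP", 4, 8, output_activation = "softmax",
                            error_function = "SOS"), "SOS")
  sp <- network_spec("MLP", 9, 40)
  expect_equal(network_name(sp), "MLP 9-40-2")
})

test_that("the MLP separates blob data and is reproducible", {
  bl <- blob_data(sep = 8, seed = 1)
  sp <- split_dataset(bl$y, seed = 2)
  m1 <- train_mlp(network_spec("MLP", 2, 8), bl$X[sp$train, ], bl$y[sp$train],
                  bl$X[sp$validation, ], bl$y[sp$validation], seed = 3)
  m2 <- train_mlp(network_spec("MLP", 2, 8), bl$X[sp$train, ], bl$y[sp$train],
                  bl$X[sp$validation, ], bl$y[sp$validation], seed = 3)
  expect_identical(m1$theta, m2$theta)
  expect_equal(mean(predict_class(m1, bl$X[sp$train, ]) == bl$y[sp$train]), 1)
  # SOS error with exponential output trains too
  m3 <- train_mlp(network_spec("MLP", 2, 8, "linear", "exponential", "SOS"),
                  bl$X[sp$train, ], bl$y[sp$train], seed = 3)
  expect_gte(mean(predict_class(m3, bl$X[sp$test, ]) == bl$y[sp$test]), 0.95)
})

test_that("an MLP on pure noise inputs learns the class priors", {
  set.seed(6)
  y <- c(rep("HC", 150), rep("OA", 50))        # 75/25 priors
  X <- matrix(0, 200, 3)
  m <- train_mlp(network_spec("MLP", 3, 4, max_iter = 200L), X, y, seed = 2)
  P <- predict_proba(m, X)
  expect_equal(unname(colMeans(P)), c(0.75, 0.25), tolerance = 0.02)
})

test_that("the RBF network separates blobs and interpolates at full capacity", {
  bl <- blob_data(sep = 8, seed = 4)
  sp <- split_dataset(bl$y, seed = 5)
  r1 <- train_rbf(network_spec("RBF", 2, 20), bl$X[sp$train, ], bl$y[sp$train],
                  seed = 6)
  r2 <- train_rbf(network_spec("RBF", 2, 20), bl$X[sp$train, ], bl$y[sp$train],
                  seed = 6)
  expect_identical(r1$out_weights, r2$out_weights)
  expect_gte(mean(predict_class(r1, bl$X[sp$test, ]) == bl$y[sp$test]), 0.95)
  ri <- train_rbf(network_spec("RBF", 2, length(sp$train), max_iter = 400L),
                  bl$X[sp$train, ], bl$y[sp$train], seed = 6,
                  width_scale = 0.1)
  expect_equal(mean(predict_class(ri, bl$X[sp$train, ]) == bl$y[sp$train]), 1)
  Pown <- predict_proba(ri, bl$X[sp$train, ])
  expect_true(all(Pown[cbind(seq_along(sp$train),
                             match(bl$y[sp$train], ri$levels))] > 0.5))
  expect_error(train_rbf(network_spec("RBF", 2, 500), bl$X[sp$train, ],
                         bl$y[sp$train]), "exceeds")
})

test_that("probabilities are proper and invariant to column scaling", {
  bl <- blob_data(sep = 8, seed = 7)
  sp <- split_dataset(bl$y, seed = 8)
  for (fam in c("MLP", "RBF")) {
    m <- if (fam == "MLP")
      train_mlp(network_spec("MLP", 2, 6), bl$X[sp$train, ], bl$y[sp$train],
                seed = 9)
    else
      train_rbf(network_spec("RBF", 2, 10), bl$X[sp$train, ], bl$y[sp$train],
                seed = 9)
    P <- predict_proba(m, bl$X)
    expect_true(all(P >= 0 & P <= 1))
    expect_equal(rowSums(P), rep(1, nrow(P)), tolerance = 1e-12)
    # scaling a raw feature column is absorbed by the training scaler
    Xs <- bl$X; Xs[, 1] <- 10 * Xs[, 1]
    ms <- if (fam == "MLP")
      train_mlp(network_spec("MLP", 2, 6), Xs[sp$train, ], bl$y[sp$train],
                seed = 9)
    else
      train_rbf(network_spec("RBF", 2, 10), Xs[sp$train, ], bl$y[sp$train],
                seed = 9)
    expect_equal(predict_proba(ms, Xs), P, tolerance = 1e-8)
    expect_error(predict_proba(m, bl$X[, 1, drop = FALSE]), "dimension")
  }
})

test_that("model search ranks candidates and formats the leaderboard", {
  bl <- blob_data(sep = 8, seed = 10)
  sp <- split_dataset(bl$y, seed = 11)
  one <- model_search(bl$X, bl$y, sp, "RBF", hidden_grid = 12, seed = 12)
  expect_equal(nrow(one$leaderboard), 1)
  expect_equal(network_name(one$best), "RBF 2-12-2")
  ms <- model_search(bl$X, bl$y, sp, "MLP", hidden_grid = c(4, 8), seed = 12)
  expect_true(all(grepl("^MLP 2-\\d+-2$", ms$leaderboard$name)))
  expect_equal(ms$leaderboard$validation_acc[1],
               max(ms$leaderboard$validation_acc))
  expect_gte(max(ms$leaderboard$validation_acc),
             ms$leaderboard$validation_acc[nrow(ms$leaderboard)])
})
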