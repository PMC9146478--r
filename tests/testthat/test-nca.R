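test_that("weighted distance and kernel follow their closed forms", {
  expect_equal(nca_distance(c(1, 2), c(1, 2), c(3, 4)), 0)
  expect_equal(nca_distance(c(1, 0), c(0, 2), c(0, 0)), 0)
  expect_equal(nca_distance(c(1, 0), c(0, 2), c(1, 2)), 9)  # 1*1 + 4*2
  expect_equal(nca_kernel(0, 2), 1)
  expect_equal(nca_kernel(1, 1), exp(-1))
  expect_lt(nca_kernel(2, 1), nca_kernel(1, 1))
  expect_error(nca_kernel(1, 0), "sigma")
})

test_that("leave-one-out probabilities are row-stochastic with exact limits", {
  set.seed(2)
  X <- matrix(rnorm(40), 10, 4)
  y <- rep(c("a", "b"), 5)
  for (i in 1:5) {
    w <- runif(4, 0, 3)
    lp <- nca_loo_probabilities(X, y, w, sigma = runif(1, 0.5, 2))
    expect_true(all(diag(lp$p_ij) == 0))
    expect_equal(rowSums(lp$p_ij), rep(1, 10), tolerance = 1e-12)
    expect_true(all(lp$p_i >= 0 & lp$p_i <= 1))
  }
  # w = 0: uniform neighbor probabilities and exact p_i
  lp0 <- nca_loo_probabilities(X, y, rep(0, 4))
  expect_equal(lp0$p_ij[1, -1], rep(1 / 9, 9), tolerance = 1e-14,
               ignore_attr = TRUE)
  expect_equal(lp0$p_i, rep((5 - 1) / (10 - 1), 10), tolerance = 1e-14)
  # two points: same class -> p = 1, different class -> p = 0
  X2 <- matrix(c(0, 1, 0, 1), 2, 2)
  expect_equal(nca_loo_probabilities(X2, c("a", "a"), c(1, 1))$p_i, c(1, 1))
  expect_equal(nca_loo_probabilities(X2, c("a", "b"), c(1, 1))$p_i, c(0, 0))
})

test_that("the objective matches its components and penalty monotonicity", {
  set.seed(3)
  X <- matrix(rnorm(36), 12, 3)
  y <- rep(c("a", "a", "b"), 4)
  # w = 0: objective is sum of (n_class - 1)/(N - 1), any lambda
  f0 <- sum((table(y)[y] - 1) / (12 - 1))
  expect_equal(nca_objective(X, y, rep(0, 3), lam = 5), unname(f0))
  w <- runif(3, 0.5, 2)
  expect_equal(nca_objective(X, y, w, lam = 0),
               sum(nca_loo_probabilities(X, y, w)$p_i))
  expect_lt(nca_objective(X, y, w, lam = 2), nca_objective(X, y, w, lam = 1))
})

test_that("the analytic gradient matches central finite differences", {
  set.seed(4)
  for (rep in 1:5) {
    N <- sample(6:12, 1); d <- sample(2:5, 1)
    X <- matrix(rnorm(N * d), N, d)
    y <- sample(c("a", "b"), N, replace = TRUE)
    if (length(unique(y)) < 2) y[1:2] <- c("a", "b")
    w <- runif(d, 0.1, 2); sig <- runif(1, 0.5, 2); lam <- runif(1, 0, 1)
    g <- nca_gradient(X, y, w, sig, lam)
    h <- 1e-6
    fd <- vapply(seq_len(d), function(l) {
      wp <- w; wm <- w; wp[l] <- w[l] + h; wm[l] <- w[l] - h
      (nca_objective(X, y, wp, sig, lam) -
         nca_objective(X, y, wm, sig, lam)) / (2 * h)
    }, numeric(1))
    expect_lt(max(abs(g - fd) / pmax(abs(fd), 1e-8)), 1e-5)
    expect_equal(nca_gradient(X, y, rep(0, d), sig, lam), rep(0, d))
  }
  # pure penalty: identical points freeze the kernel term
  Xc <- matrix(1, 6, 3)
  yc <- rep(c("a", "b"), 3)
  w <- c(0.3, 1.1, 2)
  expect_equal(nca_gradient(Xc, yc, w, 1, 0.7), -2 * 0.7 * w,
               tolerance = 1e-10)
})

test_that("NCA recovers the informative feature and shrinks with lambda", {
  fx <- recovery_fixture()
  model <- fit_nca(fx$X, fx$y, seed = 1)
  w2 <- model$w^2
  expect_equal(which.max(w2), 1L)
  expect_gt(w2[1], max(w2[2:5]))
  expect_true(1L %in% model$selected)
  expect_gte(sum(!(2:5 %in% model$selected)), 2)    # >= half the noise dropped
  # lambda-shrinkage of the total weight mass at the optimum
  st <- vagdx:::.standardize(fx$X)
  mass <- vapply(c(0.001, 0.01, 0.1, 1), function(lam)
    sum(vagdx:::.nca_ascent(st$X, fx$y, 1, lam)$w^2), numeric(1))
  expect_true(all(diff(mass) <= 1e-8))
  # duplicate feature: combined mass on the informative pair beats noise
  Xd <- fx$X; Xd[, 2] <- Xd[, 1]
  md <- fit_nca(Xd, fx$y, seed = 1)
  expect_gt(sum(md$w[1:2]^2), sum(md$w[3:5]^2))
})

test_that("permuted labels never beat the informative-feature weight", {
  fx <- recovery_fixture()
  ref <- fit_nca(fx$X, fx$y, seed = 1)
  set.seed(33)
  for (i in 1:3) {
    mp <- fit_nca(fx$X, sample(fx$y), seed = 1)
    expect_lt(max(mp$w^2), ref$w[1]^2)
  }
})

test_that("feature selection thresholds on the squared-weight fraction", {
  fake <- structure(list(w = c(3, 0.1, 0.05), threshold_frac = 0.1),
                    class = "vag_nca")
  expect_equal(select_features(fake, 0.1), 1L)
  expect_equal(select_features(fake, 0), 1:3)
  fake$w <- c(1, 1, 1)
  expect_equal(select_features(fake, 0.9), 1:3)
  fake$w <- c(0, 0, 0)
  expect_warning(sel <- select_features(fake, 0.1), "zero")
  expect_length(sel, 0)
})
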