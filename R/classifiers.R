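#' Network specification
#'
#' Describes one feed-forward network of either family: a multilayer
#' perceptron (MLP) with one hidden layer, or a radial-basis-function (RBF)
#' network with Gaussian hidden units around selected centers. The name
#' convention `FAMILY n_in-n_hidden-2` reports input, hidden, and output
#' neuron counts.
#'
#' @param family `"MLP"` or `"RBF"`.
#' @param n_in input count.
#' @param n_hidden hidden-unit count.
#' @param hidden_activation for MLP one of `"linear"`, `"logistic"`,
#'   `"tanh"`, `"exponential"`, `"gauss"`; RBF networks always use `"gauss"`.
#' @param output_activation `"softmax"`, `"exponential"`, or `"linear"`.
#' @param error_function `"entropy"` (cross-entropy, requires softmax output)
#'   or `"SOS"` (sum of squares, with linear or exponential output).
#' @param max_iter training iteration cap (the "BFGS k" of the name reports
#'   the cap actually consumed).
#' @return an object of class `vag_netspec`.
#' @export
network_spec <- function(family, n_in, n_hidden,
                         hidden_activation = if (family == "RBF") "gauss" else "logistic",
                         output_activation = "softmax",
                         error_function = "entropy",
                         max_iter = 100L) {
  family <- match.arg(family, c("MLP", "RBF"))
  hidden_activation <- match.arg(hidden_activation,
                                 c("linear", "logistic", "tanh", "exponential", "gauss"))
  output_activation <- match.arg(output_activation,
                                 c("softmax", "exponential", "linear"))
  error_function <- match.arg(error_function, c("entropy", "SOS"))
  if (family == "RBF" && hidden_activation != "gauss")
    stop("RBF networks use the Gaussian hidden activation")
  if (error_function == "entropy" && output_activation != "softmax")
    stop("the entropy error function requires the softmax output activation")
  if (error_function == "SOS" && output_activation == "softmax")
    stop("the SOS error function is used with linear or exponential outputs")
  structure(list(family = family, n_in = as.integer(n_in),
                 n_hidden = as.integer(n_hidden), n_out = 2L,
                 hidden_activation = hidden_activation,
                 output_activation = output_activation,
                 error_function = error_function,
                 max_iter = as.integer(max_iter)),
            class = "vag_netspec")
}

#' Network name in `FAMILY n_in-n_hidden-2` format
#' @param spec a `vag_netspec` or trained network.
#' @return character scalar, e.g. `"MLP 9-40-2"`.
#' @export
network_name <- function(spec) {
  if (inherits(spec, "vag_network")) spec <- spec$spec
  sprintf("%s %d-%d-%d", spec$family, spec$n_in, spec$n_hidden, spec$n_out)
}

#' Split a dataset into training, test, and validation sets
#'
#' Random 70/15/15 split (by default), optionally stratified by label using
#' per-class quotas (largest-remainder apportionment), deterministic given
#' `seed`. The three index sets are disjoint and exhaustive.
#'
#' @param y labels, length N >= 10.
#' @param fractions named fractions summing to 1
#'   (`c(train = .7, test = .15, validation = .15)`).
#' @param seed integer seed.
#' @param stratified stratify by label (default TRUE).
#' @return list of integer index vectors `train`, `test`, `validation`.
#' @export
split_dataset <- function(y, fractions = c(train = 0.70, test = 0.15,
                                           validation = 0.15),
                          seed = 1L, stratified = TRUE) {
  N <- length(y)
  if (N < 10) stop("need at least 10 cases to split")
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  n_te <- round(fractions[["test"]] * N)
  n_va <- round(fractions[["validation"]] * N)
  set.seed(seed)
  if (!stratified) {
    idx <- sample.int(N)
    return(list(train = sort(idx[seq_len(N - n_te - n_va)]),
                test = sort(idx[N - n_te - n_va + seq_len(n_te)]),
                validation = sort(idx[N - n_va + seq_len(n_va)])))
  }
  classes <- unique(y)
  quota <- function(target) {
    share <- target * vapply(classes, function(cl) sum(y == cl), 0) / N
    base <- floor(share)
    extra <- target - sum(base)
    if (extra > 0)
      base[order(share - base, decreasing = TRUE)[seq_len(extra)]] <-
        base[order(share - base, decreasing = TRUE)[seq_len(extra)]] + 1
    base
  }
  q_te <- quota(n_te); q_va <- quota(n_va)
  te <- va <- tr <- integer(0)
  for (ci in seq_along(classes)) {
    members <- sample(which(y == classes[ci]))
    if (length(members) - q_te[ci] - q_va[ci] < 1)
      stop("stratified split leaves class ", classes[ci],
           " empty in the training set")
    te <- c(te, members[seq_len(q_te[ci])])
    va <- c(va, members[q_te[ci] + seq_len(q_va[ci])])
    tr <- c(tr, members[-seq_len(q_te[ci] + q_va[ci])])
  }
  list(train = sort(tr), test = sort(te), validation = sort(va))
}

# activation functions and derivatives (derivative expressed via z and h)
.act <- function(z, kind) {
  switch(kind, linear = z, logistic = 1 / (1 + exp(-z)), tanh = tanh(z),
         exponential = exp(z), gauss = exp(-z^2))
}
.act_deriv <- function(z, h, kind) {
  switch(kind, linear = 1 + 0 * z, logistic = h * (1 - h), tanh = 1 - h^2,
         exponential = h, gauss = -2 * z * h)
}
.softmax <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

.onehot <- function(y, levels) {
  Y <- matrix(0, length(y), length(levels))
  Y[cbind(seq_along(y), match(y, levels))] <- 1
  Y
}

# MLP loss and analytic gradient over flattened parameters
.mlp_unpack <- function(theta, n_in, n_h) {
  i <- 0
  W1 <- matrix(theta[i + seq_len(n_in * n_h)], n_in, n_h); i <- i + n_in * n_h
  b1 <- theta[i + seq_len(n_h)]; i <- i + n_h
  W2 <- matrix(theta[i + seq_len(n_h * 2)], n_h, 2); i <- i + n_h * 2
  b2 <- theta[i + seq_len(2)]
  list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
}

.mlp_forward <- function(p, X, spec) {
  Z1 <- sweep(X %*% p$W1, 2, p$b1, "+")
  H <- .act(Z1, spec$hidden_activation)
  Z2 <- sweep(H %*% p$W2, 2, p$b2, "+")
  O <- switch(spec$output_activation,
              softmax = .softmax(Z2), exponential = exp(Z2), linear = Z2)
  list(Z1 = Z1, H = H, Z2 = Z2, O = O)
}

.mlp_loss <- function(theta, X, Y, spec, decay = 0) {
  p <- .mlp_unpack(theta, spec$n_in, spec$n_hidden)
  fw <- .mlp_forward(p, X, spec)
  err <- if (spec$error_function == "entropy")
    -sum(Y * log(pmax(fw$O, 1e-300)))
  else
    sum((fw$O - Y)^2)
  err + 0.5 * decay * (sum(p$W1^2) + sum(p$W2^2))
}

.mlp_grad <- function(theta, X, Y, spec, decay = 0) {
  p <- .mlp_unpack(theta, spec$n_in, spec$n_hidden)
  fw <- .mlp_forward(p, X, spec)
  dZ2 <- if (spec$error_function == "entropy") fw$O - Y
         else switch(spec$output_activation,
                     exponential = 2 * (fw$O - Y) * fw$O,
                     linear = 2 * (fw$O - Y))
  dW2 <- t(fw$H) %*% dZ2 + decay * p$W2
  db2 <- colSums(dZ2)
  dZ1 <- (dZ2 %*% t(p$W2)) * .act_deriv(fw$Z1, fw$H, spec$hidden_activation)
  c(as.vector(t(X) %*% dZ1 + decay * p$W1), colSums(dZ1), as.vector(dW2), db2)
}

#' Train a multilayer perceptron
#'
#' One hidden layer with the configured activation, trained by the BFGS
#' quasi-Newton optimizer on the configured error function (cross-entropy
#' with softmax outputs, or sum-of-squares with linear/exponential outputs).
#' Inputs are standardized with training-set statistics. Training runs in
#' short BFGS segments up to `spec$max_iter` total iterations; when a
#' validation set is supplied, the iterate with the lowest validation error
#' is retained.
#'
#' @param spec a `vag_netspec` with `family = "MLP"`.
#' @param X,y training features (matrix) and labels.
#' @param X_val,y_val optional validation set for best-iterate selection.
#' @param seed integer seed for the weight initialization (uniform in
#'   `+/- sqrt(6 / (fan_in + fan_out))`).
#' @param decay L2 penalty on the connection weights (biases excluded); keeps
#'   the cross-entropy optimum finite on linearly separable training sets,
#'   preventing arbitrarily confident extrapolation.
#' @return an object of class `vag_network`.
#' @export
train_mlp <- function(spec, X, y, X_val = NULL, y_val = NULL, seed = 1L,
                      decay = 0.01) {
  stopifnot(inherits(spec, "vag_netspec"), spec$family == "MLP")
  X <- as.matrix(X)
  if (ncol(X) != spec$n_in) stop("n_in does not match data")
  levels <- sort(unique(as.character(y)))
  st <- .standardize(X)
  Y <- .onehot(as.character(y), levels)
  n_h <- spec$n_hidden
  set.seed(seed)
  r1 <- sqrt(6 / (spec$n_in + n_h)); r2 <- sqrt(6 / (n_h + 2))
  theta <- c(runif(spec$n_in * n_h, -r1, r1), rep(0, n_h),
             runif(n_h * 2, -r2, r2), rep(0, 2))
  Xv <- if (!is.null(X_val))
    sweep(sweep(as.matrix(X_val), 2, st$center), 2, st$scale, "/")
  Yv <- if (!is.null(X_val)) .onehot(as.character(y_val), levels)
  best <- theta
  best_val <- if (!is.null(Xv)) .mlp_loss(theta, Xv, Yv, spec) else Inf
  log <- numeric(0)
  used <- 0L
  seg <- 5L
  while (used < spec$max_iter) {
    k <- min(seg, spec$max_iter - used)
    fit <- optim(theta, .mlp_loss, .mlp_grad, X = st$X, Y = Y, spec = spec,
                 decay = decay, method = "BFGS", control = list(maxit = k))
    theta <- fit$par
    used <- used + k
    log <- c(log, fit$value)
    if (!is.null(Xv)) {
      v <- .mlp_loss(theta, Xv, Yv, spec)
      if (v < best_val) { best_val <- v; best <- theta }
    } else best <- theta
    if (fit$convergence == 0) break
  }
  if (!is.finite(.mlp_loss(best, st$X, Y, spec)))
    stop("non-finite MLP training loss; check inputs and spec")
  structure(list(spec = spec, theta = best,
                 parameters = .mlp_unpack(best, spec$n_in, n_h),
                 input_scaler = st[c("center", "scale")], levels = levels,
                 training_log = log, iterations = used),
            class = "vag_network")
}

#' Train a radial-basis-function network
#'
#' Centers are chosen by k-means on the standardized training inputs (the
#' training points themselves when `n_hidden` equals the training size); each
#' center's Gaussian width is `width_scale` times the mean distance to its 2
#' nearest fellow centers; the softmax output layer is then fit by BFGS on
#' the ridge-penalized cross-entropy -- a convex problem. The small weight
#' penalty (`decay`) keeps the output weights finite when the hidden features
#' separate the classes perfectly (unpenalized cross-entropy has no finite
#' optimum there, which produces arbitrary confident extrapolation far from
#' the centers).
#'
#' @param spec a `vag_netspec` with `family = "RBF"`.
#' @inheritParams train_mlp
#' @param width_scale multiplier on the per-center widths (small values give
#'   near-interpolating networks).
#' @param decay L2 penalty on the output weights (bias excluded).
#' @return an object of class `vag_network`.
#' @export
train_rbf <- function(spec, X, y, X_val = NULL, y_val = NULL, seed = 1L,
                      width_scale = 1, decay = 0.01) {
  stopifnot(inherits(spec, "vag_netspec"), spec$family == "RBF")
  X <- as.matrix(X)
  if (ncol(X) != spec$n_in) stop("n_in does not match data")
  if (spec$n_hidden > nrow(X))
    stop("n_hidden exceeds the number of training points")
  levels <- sort(unique(as.character(y)))
  st <- .standardize(X)
  set.seed(seed)
  centers <- if (spec$n_hidden == nrow(X)) st$X
             else kmeans(st$X, centers = spec$n_hidden, nstart = 5,
                         iter.max = 100)$centers
  cd <- as.matrix(dist(centers))
  diag(cd) <- Inf
  widths <- width_scale * apply(cd, 1, function(r) mean(sort(r)[1:min(2, length(r) - 1)]))
  widths[!is.finite(widths) | widths == 0] <- width_scale
  Hfun <- function(Xs) {
    D2 <- outer(rowSums(Xs^2), rowSums(centers^2), "+") -
      2 * Xs %*% t(centers)
    exp(-pmax(D2, 0) / (2 * rep(widths^2, each = nrow(Xs))))
  }
  H <- cbind(1, Hfun(st$X))
  Y <- .onehot(as.character(y), levels)
  nb <- ncol(H)
  mask <- c(0, rep(1, nb - 1))                 # no penalty on the bias
  loss <- function(b) {
    B <- matrix(b, nb, 2)
    P <- .softmax(H %*% B)
    -sum(Y * log(pmax(P, 1e-300))) + 0.5 * decay * sum((mask * B)^2)
  }
  grad <- function(b) {
    B <- matrix(b, nb, 2)
    P <- .softmax(H %*% B)
    as.vector(t(H) %*% (P - Y) + decay * (mask * B))
  }
  fit <- optim(rep(0, nb * 2), loss, grad, method = "BFGS",
               control = list(maxit = spec$max_iter))
  structure(list(spec = spec, centers = centers, widths = widths,
                 out_weights = matrix(fit$par, nb, 2), Hfun = Hfun,
                 input_scaler = st[c("center", "scale")], levels = levels,
                 training_log = fit$value, iterations = spec$max_iter),
            class = "vag_network")
}

#' @export
print.vag_network <- function(x, ...) {
  cat(sprintf("<vag_network> %s (%s/%s/%s)\n", network_name(x),
              x$spec$error_function, x$spec$hidden_activation,
              x$spec$output_activation))
  invisible(x)
}

#' Class probabilities from a trained network
#'
#' Inputs are rescaled with the network's own training scaler. Rows of the
#' result sum to 1: softmax outputs directly, exponential outputs after
#' normalization, linear outputs through a softmax map.
#'
#' @param model a `vag_network`.
#' @param X feature matrix with `spec$n_in` columns.
#' @return matrix (cases x 2) of class probabilities, columns named by the
#'   class levels.
#' @export
predict_proba <- function(model, X) {
  stopifnot(inherits(model, "vag_network"))
  X <- as.matrix(X)
  if (ncol(X) != model$spec$n_in) stop("input dimension mismatch")
  Xs <- sweep(sweep(X, 2, model$input_scaler$center), 2,
              model$input_scaler$scale, "/")
  P <- if (model$spec$family == "MLP") {
    fw <- .mlp_forward(model$parameters, Xs, model$spec)
    switch(model$spec$output_activation,
           softmax = fw$O,
           exponential = fw$O / rowSums(fw$O),
           linear = .softmax(fw$O))
  } else {
    .softmax(cbind(1, model$Hfun(Xs)) %*% model$out_weights)
  }
  colnames(P) <- model$levels
  P
}

#' Predicted class labels (argmax of [predict_proba()])
#' @inheritParams predict_proba
#' @return character vector of labels.
#' @export
predict_class <- function(model, X) {
  P <- predict_proba(model, X)
  model$levels[max.col(P, ties.method = "first")]
}

.accuracy_pct <- function(model, X, y)
  100 * mean(predict_class(model, X) == as.character(y))

#' Search a grid of network candidates
#'
#' Trains every candidate in a documented grid (hidden sizes for both
#' families; MLP additionally over logistic/tanh hidden activations with the
#' entropy error), ranks by validation accuracy, and returns the best network
#' together with a leaderboard reporting learning/testing/validation accuracy
#' per candidate.
#'
#' @param X,y full feature matrix and labels.
#' @param split index sets from [split_dataset()].
#' @param family `"MLP"` or `"RBF"`.
#' @param hidden_grid hidden-unit counts to try.
#' @param seed integer seed (candidate `i` trains with `seed + i`).
#' @param max_iter training iteration cap per candidate.
#' @return list: `best` (a `vag_network`), `leaderboard` (data.frame with
#'   name, accuracies, algorithm, error and activation columns).
#' @export
model_search <- function(X, y, split, family = c("MLP", "RBF"),
                         hidden_grid = c(3, 8, 16, 35), seed = 1L,
                         max_iter = 100L) {
  family <- match.arg(family)
  X <- as.matrix(X)
  y <- as.character(y)
  if (length(hidden_grid) == 0) stop("empty hidden grid")
  specs <- list()
  for (h in hidden_grid) {
    if (family == "MLP") {
      for (act in c("logistic", "tanh"))
        specs[[length(specs) + 1]] <-
          network_spec("MLP", ncol(X), h, act, "softmax", "entropy", max_iter)
    } else {
      specs[[length(specs) + 1]] <-
        network_spec("RBF", ncol(X), min(h, length(split$train)),
                     "gauss", "softmax", "entropy", max_iter)
    }
  }
  rows <- list(); models <- list()
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    m <- if (family == "MLP")
      train_mlp(sp, X[split$train, , drop = FALSE], y[split$train],
                X[split$validation, , drop = FALSE], y[split$validation],
                seed = seed + i)
    else
      train_rbf(sp, X[split$train, , drop = FALSE], y[split$train],
                seed = seed + i)
    models[[i]] <- m
    rows[[i]] <- data.frame(
      name = network_name(m),
      learning_acc = .accuracy_pct(m, X[split$train, , drop = FALSE], y[split$train]),
      testing_acc = .accuracy_pct(m, X[split$test, , drop = FALSE], y[split$test]),
      validation_acc = .accuracy_pct(m, X[split$validation, , drop = FALSE],
                                     y[split$validation]),
      algorithm = if (family == "MLP") sprintf("BFGS %d", m$iterations) else "RBFT",
      error_function = sp$error_function,
      activation_hidden = sp$hidden_activation,
      activation_output = sp$output_activation)
  }
  leaderboard <- do.call(rbind, rows)
  # rank by validation accuracy only; ties keep grid order (test-set
  # performance must play no part in model selection)
  ord <- order(-leaderboard$validation_acc, seq_len(nrow(leaderboard)))
  list(best = models[[ord[1]]], leaderboard = leaderboard[ord, ])
}
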