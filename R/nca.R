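#' Weighted L1 distance with squared per-feature weights
#'
#' `D_w(xi, xj) = sum_l w_l^2 * |x_il - x_jl|`. Squaring the weights keeps the
#' distance non-negative without constraining the optimizer.
#'
#' @param xi,xj feature vectors of equal length.
#' @param w weight vector, same length.
#' @return non-negative scalar.
#' @export
nca_distance <- function(xi, xj, w) {
  stopifnot(length(xi) == length(xj), length(xi) == length(w))
  sum(w^2 * abs(xi - xj))
}

#' Exponential neighborhood kernel
#'
#' `kappa(z) = exp(-z / sigma)`; `sigma` is the kernel width -- larger widths
#' decay more slowly, spreading reference-point probability over more
#' neighbors.
#'
#' @param z non-negative distance(s).
#' @param sigma kernel width, > 0.
#' @return value(s) in (0, 1].
#' @export
nca_kernel <- function(z, sigma) {
  if (sigma <= 0) stop("sigma must be > 0")
  exp(-z / sigma)
}

# Pairwise weighted-distance matrix (N x N) for weight vector w.
.nca_dist_matrix <- function(X, w) {
  N <- nrow(X)
  D <- matrix(0, N, N)
  for (l in seq_len(ncol(X)))
    D <- D + w[l]^2 * abs(outer(X[, l], X[, l], "-"))
  D
}

#' Leave-one-out soft-neighbor probabilities
#'
#' `p_ij` is the probability that point `i` picks point `j` as its reference
#' neighbor (`p_ii = 0`, rows sum to 1), and `p_i = sum_j y_ij p_ij` is the
#' probability that `i` is correctly classified by its soft nearest neighbor,
#' where `y_ij` indicates same-class pairs.
#'
#' @param X numeric matrix (N x d).
#' @param y class labels, length N.
#' @param w feature weights, length d.
#' @param sigma kernel width.
#' @return list: `p_ij` (N x N matrix), `p_i` (length-N vector).
#' @export
nca_loo_probabilities <- function(X, y, w, sigma = 1) {
  N <- nrow(X)
  if (N < 2) stop("need at least 2 observations")
  D <- .nca_dist_matrix(X, w)
  # shift each row by its smallest off-diagonal distance before applying the
  # kernel: the normalization cancels the shift exactly, but keeps the row
  # sums >= 1 when all distances are large (numerical stability)
  diag(D) <- Inf
  D <- D - apply(D, 1, min)
  K <- nca_kernel(D, sigma)
  diag(K) <- 0
  P <- K / rowSums(K)
  Y <- outer(y, y, "==")
  list(p_ij = P, p_i = rowSums(P * Y))
}

#' Regularized NCA objective
#'
#' `F(w) = sum_i p_i - lambda * sum_l w_l^2`: expected leave-one-out
#' classification accuracy minus an L2 penalty on the weights.
#'
#' @inheritParams nca_loo_probabilities
#' @param lam regularization strength, >= 0.
#' @return scalar objective value.
#' @export
nca_objective <- function(X, y, w, sigma = 1, lam = 0) {
  sum(nca_loo_probabilities(X, y, w, sigma)$p_i) - lam * sum(w^2)
}

#' Analytic gradient of the NCA objective
#'
#' Derived from the objective by the chain rule (every term carries the
#' factor `w_l`, so the gradient vanishes at `w = 0`):
#' `dF/dw_l = (2 w_l / sigma) * sum_i [ p_i * sum_k p_ik |x_il - x_kl|
#'   - sum_j y_ij p_ij |x_il - x_jl| ] - 2 lambda w_l`.
#'
#' @inheritParams nca_objective
#' @return gradient vector of length d.
#' @export
nca_gradient <- function(X, y, w, sigma = 1, lam = 0) {
  lp <- nca_loo_probabilities(X, y, w, sigma)
  P <- lp$p_ij
  Y <- outer(y, y, "==")
  PY <- P * Y
  g <- numeric(ncol(X))
  for (l in seq_len(ncol(X))) {
    Al <- abs(outer(X[, l], X[, l], "-"))
    g[l] <- (2 * w[l] / sigma) *
      (sum(lp$p_i * rowSums(P * Al)) - sum(PY * Al)) - 2 * lam * w[l]
  }
  g
}

# Gradient ascent with backtracking line search; the objective never
# decreases along accepted steps. Returns the fitted weights and the
# objective trace.
.nca_ascent <- function(X, y, sigma, lam, w0 = rep(1, ncol(X)),
                        max_iter = 400L, tol = 1e-6) {
  w <- w0
  f <- nca_objective(X, y, w, sigma, lam)
  trace <- f
  step <- 1
  for (it in seq_len(max_iter)) {
    g <- nca_gradient(X, y, w, sigma, lam)
    gn <- sqrt(sum(g^2))
    if (gn < 1e-12) break
    accepted <- FALSE
    s <- step
    for (bt in 1:30) {
      w_new <- w + s * g
      f_new <- nca_objective(X, y, w_new, sigma, lam)
      if (f_new > f) { accepted <- TRUE; break }
      s <- s / 2
    }
    if (!accepted) break
    rel <- abs(f_new - f) / (abs(f) + 1e-12)
    w <- w_new
    f <- f_new
    trace <- c(trace, f)
    step <- s * 2                       # mild step growth between iterations
    if (rel < tol) break
  }
  list(w = w, objective = f, trace = trace)
}

# Mean correct-classification probability of held-out points scored against
# a training reference set.
.nca_holdout_pi <- function(X_tr, y_tr, X_va, y_va, w, sigma) {
  p <- vapply(seq_len(nrow(X_va)), function(v) {
    D <- colSums(w^2 * abs(t(X_tr) - X_va[v, ]))
    k <- nca_kernel(D, sigma)
    sum(k[y_tr == y_va[v]]) / sum(k)
  }, numeric(1))
  mean(p)
}

.standardize <- function(X, center = NULL, scale = NULL) {
  if (is.null(center)) center <- colMeans(X)
  if (is.null(scale)) {
    scale <- apply(X, 2, sd)
    scale[scale == 0] <- 1
  }
  list(X = sweep(sweep(X, 2, center), 2, scale, "/"),
       center = center, scale = scale)
}

#' Fit NCA feature weights with cross-validated regularization
#'
#' Features are standardized (zero mean, unit variance, training folds only)
#' before weighting, since the raw inputs mix units (years, kg/m^2,
#' dimensionless moments). For each `lambda` in the grid, k-fold
#' cross-validation maximizes the regularized objective on the training folds
#' by gradient ascent and records the validation loss `1 - mean(p_i)` of the
#' held-out points scored against the training folds; the model is then refit
#' on the full data at the loss-minimizing `lambda`.
#'
#' @param X numeric matrix or data.frame (N x d) of features.
#' @param y class labels (factor or character), length N.
#' @param sigma kernel width (default 1, appropriate post-standardization).
#' @param lambda_grid regularization grid; default 13 log-spaced values in
#'   `[1e-4, 100] / N` (wide enough that the cross-validated optimum is an
#'   interior point of the grid rather than a boundary solution).
#' @param n_folds cross-validation folds (default 5).
#' @param seed integer seed for fold assignment.
#' @param threshold_frac feature-retention threshold, see [select_features()].
#' @param max_iter,tol gradient-ascent controls.
#' @return object of class `vag_nca`: weights `w`, `sigma`, chosen `lambda`,
#'   `cv_table` (per-lambda mean validation loss), `selected` feature
#'   indices, `feature_names`, standardization constants, and the final
#'   objective value.
#' @export
fit_nca <- function(X, y, sigma = 1, lambda_grid = NULL, n_folds = 5L,
                    seed = 1L, threshold_frac = 0.05,
                    max_iter = 400L, tol = 1e-6) {
  X <- as.matrix(X)
  y <- as.character(y)
  N <- nrow(X)
  if (N < n_folds || n_folds < 2) stop("need N >= n_folds >= 2")
  if (is.null(lambda_grid))
    lambda_grid <- exp(seq(log(1e-4), log(100), length.out = 13)) / N
  if (length(lambda_grid) == 0) stop("empty lambda grid")
  set.seed(seed)
  fold <- sample(rep(seq_len(n_folds), length.out = N))
  cv_loss <- vapply(lambda_grid, function(lam) {
    losses <- vapply(seq_len(n_folds), function(kf) {
      tr <- fold != kf
      st <- .standardize(X[tr, , drop = FALSE])
      fitw <- .nca_ascent(st$X, y[tr], sigma, lam,
                          max_iter = max_iter, tol = tol)
      X_va <- sweep(sweep(X[!tr, , drop = FALSE], 2, st$center), 2,
                    st$scale, "/")
      1 - .nca_holdout_pi(st$X, y[tr], X_va, y[!tr], fitw$w, sigma)
    }, numeric(1))
    mean(losses)
  }, numeric(1))
  best <- which.min(cv_loss)
  st <- .standardize(X)
  fitw <- .nca_ascent(st$X, y, sigma, lambda_grid[best],
                      max_iter = max_iter, tol = tol)
  model <- structure(list(
    w = fitw$w, sigma = sigma, lambda = lambda_grid[best],
    cv_table = data.frame(lambda = lambda_grid, loss = cv_loss),
    feature_names = colnames(X) %||% paste0("f", seq_len(ncol(X))),
    center = st$center, scale = st$scale,
    objective = fitw$objective, trace = fitw$trace,
    threshold_frac = threshold_frac
  ), class = "vag_nca")
  model$selected <- select_features(model, threshold_frac)
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Select features from a fitted NCA model
#'
#' Retains feature `l` when `w_l^2 >= threshold_frac * max(w^2)`.
#'
#' @param model a `vag_nca` from [fit_nca()].
#' @param threshold_frac fraction of the maximal squared weight (default the
#'   model's own).
#' @return integer vector of retained feature indices (empty, with a warning,
#'   when all weights are zero).
#' @export
select_features <- function(model, threshold_frac = model$threshold_frac) {
  w2 <- model$w^2
  if (max(w2) == 0) {
    warning("all NCA weights are zero; no features selected")
    return(integer(0))
  }
  which(w2 >= threshold_frac * max(w2))
}

#' @export
print.vag_nca <- function(x, ...) {
  cat(sprintf("<vag_nca> sigma=%g lambda=%.3g objective=%.4f\n",
              x$sigma, x$lambda, x$objective))
  tab <- data.frame(feature = x$feature_names, w = x$w, w2 = x$w^2,
                    selected = seq_along(x$w) %in% x$selected)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Export the NCA weight table
#'
#' One row per feature: name, weight, squared weight, selected flag --
#' bar-chart-ready in the style of NCA feature-importance plots.
#'
#' @param model a `vag_nca`.
#' @param path optional CSV output path.
#' @return the weight table data.frame (invisibly writes `path` if given).
#' @export
nca_weight_table <- function(model, path = NULL) {
  tab <- data.frame(feature = model$feature_names, w = model$w, w2 = model$w^2,
                    selected = seq_along(model$w) %in% model$selected)
  if (!is.null(path)) write.csv(tab, path, row.names = FALSE, quote = FALSE)
  tab
}
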