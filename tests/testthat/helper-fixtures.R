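# Shared fixtures, built in code at test time.

# two superimposed tones, 1400 Hz sampling
two_tone <- function(f1 = 5, f2 = 50, a1 = 0.8, a2 = 1, fs = 1400, dur = 2) {
  t <- seq(0, dur, by = 1 / fs)
  list(t = t, x = a1 * sin(2 * pi * f1 * t) + a2 * sin(2 * pi * f2 * t),
       tone1 = a1 * sin(2 * pi * f1 * t), tone2 = a2 * sin(2 * pi * f2 * t))
}

# two well-separated Gaussian blobs (linearly separable by construction for
# large sep), labels HC/OA
blob_data <- function(n = 200, sep = 8, seed = 1) {
  set.seed(seed)
  y <- rep(c("HC", "OA"), each = n / 2)
  X <- cbind(rnorm(n) + ifelse(y == "OA", sep, 0), rnorm(n))
  list(X = X, y = y)
}

# one informative feature + four i.i.d. noise features
recovery_fixture <- function(n = 60, seed = 7) {
  set.seed(seed)
  y <- rep(c("HC", "OA"), each = n / 2)
  X <- cbind(ifelse(y == "OA", 1.5, -1.5) + rnorm(n, 0, 0.5),
             matrix(rnorm(n * 4), n, 4))
  colnames(X) <- paste0("f", 1:5)
  list(X = X, y = y)
}

# small, fast generator configuration for structural tests
small_config <- function(...) {
  args <- utils::modifyList(list(n_hc = 3L, n_oa = 3L, n_cycles = 3L,
                                 seed = 11L), list(...))
  do.call(vag_config, args)
}

# independent extrema / zero-crossing counters (R-side oracle for the
# IMF admissibility condition; assumes no exact ties, which holds for the
# continuous-valued signals used in tests)
oracle_n_extrema <- function(x) {
  d <- sign(diff(x))
  d <- d[d != 0]
  sum(diff(d) != 0)
}
oracle_n_zero <- function(x) {
  s <- sign(x)
  s <- s[s != 0]
  sum(diff(s) != 0)
}
imf_admissible <- function(x) abs(oracle_n_extrema(x) - oracle_n_zero(x)) <= 1

# naive direct-summation reimplementation of the 12 measures (oracle)
oracle_features <- function(x) {
  n <- length(x)
  mv <- sum(x) / n
  sa <- sum(abs(x)) / n
  rms <- sqrt(sum(x^2) / n)
  pv <- max(abs(x))
  ppv <- abs(max(x) - min(x))
  cm <- function(p) { s <- 0; for (xi in x) s <- s + (xi - mv)^p; s / n }
  m2 <- cm(2)
  c(mv = mv, sa = sa, rms = rms, pv = pv, ppv = ppv,
    cf = pv / rms, "if" = pv / mv, sf = rms / sa,
    var = sum((x - mv)^2) / (n - 1),
    kur = cm(4) / m2^2, m6a = cm(6) / m2^3, m8a = cm(8) / m2^4)
}
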