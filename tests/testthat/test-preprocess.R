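test_that("cycle detection finds every generated cycle near its true onset", {
  cfg <- vag_config(n_cycles = 10L, seed = 3L)
  tr <- generate_encoder_trace(cfg, jitter_seed = 17)
  segs <- detect_cycles(as.numeric(tr), cfg$fs_encoder, cfg$fs_acoustic)
  truth <- attr(tr, "cycles")
  expect_equal(nrow(segs), 10)
  expect_true(all(diff(segs$start) > 0))
  expect_true(all(segs$end > segs$start))
  # boundaries within one encoder period of ground truth
  expect_true(all(abs(segs$start_time - truth$start_time) <= 0.1 + 1e-9))
  expect_true(all(abs(segs$end_time - truth$end_time) <= 0.1 + 1e-9))
  expect_warning(flat <- detect_cycles(rep(90, 50), 10, 1400), "no movement")
  expect_equal(nrow(flat), 0)
})

test_that("one sift step satisfies the envelope-mean identities", {
  t <- seq(0, 3, by = 1 / 500)
  x <- sin(2 * pi * 5 * t)
  s <- sift_once(x)
  inner <- seq(100, length(x) - 100)
  expect_lt(max(abs(s$m1[inner])), 0.05)            # zero-mean envelope of a sine
  s2 <- sift_once(x + 2.5)
  expect_lt(max(abs(s2$m1[inner] - 2.5)), 0.05)     # offset passes into m1
  expect_equal(s$d1 + s$m1, s$x, tolerance = 1e-14) # d1 = x - m1 exactly
  expect_equal(s$h1, s$x - s$d1, tolerance = 1e-14)
  expect_error(sift_once(seq(0, 1, 0.01)), "monotone")
})

test_that("extracted IMFs are admissible and telescoping is exact", {
  t <- seq(0, 2, by = 1 / 500)
  x <- sin(2 * pi * 20 * t)
  res <- extract_imf(x)
  expect_lt(sqrt(sum((res$imf - x)^2) / sum(x^2)), 0.05)  # sine is its own IMF
  expect_equal(res$imf + res$remainder, x, tolerance = 1e-14)
  expect_true(imf_admissible(res$imf))
})

test_that("EMD reconstructs its input exactly and orders IMFs by frequency", {
  expect_error(emd(rep(1, 100)), NA)
  const <- emd(rep(1, 100))
  expect_equal(ncol(const$imfs), 0)
  expect_equal(const$residual, rep(1, 100))

  tt <- two_tone()
  dec <- emd(tt$x)
  expect_gte(ncol(dec$imfs), 2)
  expect_gt(abs(cor(dec$imfs[, 1], tt$tone2)), 0.9)  # 50 Hz in IMF1
  low <- cbind(dec$imfs[, -1, drop = FALSE], dec$residual)
  expect_gt(max(abs(apply(low, 2, cor, y = tt$tone1))), 0.9)
  expect_lt(max(abs(rowSums(dec$imfs) + dec$residual - dec$input)),
            1e-9 * max(abs(dec$input)))
  # zero-crossing rate decreases along the IMF sequence
  zc <- apply(dec$imfs, 2, oracle_n_zero)
  expect_true(all(diff(zc) <= 0))
  # property: exact reconstruction and admissibility on random signals
  set.seed(99)
  for (i in 1:100) {
    x <- rnorm(sample(128:512, 1))
    d <- emd(x)
    expect_lt(max(abs(rowSums(d$imfs) + d$residual - x)), 1e-9 * max(abs(x)))
    expect_true(all(apply(d$imfs, 2, imf_admissible)))
  }
})

test_that("EEMD is seeded, degenerates to EMD, and averages out its noise", {
  tt <- two_tone(dur = 0.5)
  x <- tt$x
  e1 <- eemd(x, noise_std = 0.2, n_trials = 5, seed = 4)
  e2 <- eemd(x, noise_std = 0.2, n_trials = 5, seed = 4)
  expect_identical(e1$imfs, e2$imfs)
  expect_error(eemd(x, n_trials = 0), "n_trials")

  plain <- emd(x)
  tiny <- eemd(x, noise_std = 1e-12, n_trials = 1, seed = 2)
  k <- min(ncol(plain$imfs), ncol(tiny$imfs))
  expect_lt(max(abs(plain$imfs[, 1:k] - tiny$imfs[, 1:k])), 1e-6 * max(abs(x)))

  # reconstruction error shrinks as 1/sqrt(n_trials)
  sd_err <- vapply(c(1, 16, 100), function(n) {
    d <- eemd(x, noise_std = 0.2, n_trials = n, seed = 10)
    sd(rowSums(d$imfs) + d$residual - x)
  }, numeric(1))
  bound <- 3 * 0.2 * sd(x) / sqrt(c(1, 16, 100))
  expect_true(all(sd_err <= bound))
  expect_true(all(diff(sd_err) < 0))
})

test_that("detrending removes low-frequency drift", {
  set.seed(12)
  fs <- 700
  t <- seq(0, 4, by = 1 / fs)
  bursts <- numeric(length(t))
  for (t0 in seq(0.3, 3.7, by = 0.4)) {
    idx <- which(t >= t0 & t <= t0 + 0.1)
    bursts[idx] <- bursts[idx] + exp(-(t[idx] - t0) / 0.02) * sin(2 * pi * 80 * (t[idx] - t0))
  }
  drift <- 0.8 * t                                   # linear sensor drift
  x <- bursts + drift + 0.05 * rnorm(length(t))
  dec <- eemd(x, noise_std = 0.2, n_trials = 10, seed = 3)
  out <- detrend(x, dec)
  lf_energy <- function(v) {
    s <- Mod(fft(v - 0))^2
    f <- (seq_along(v) - 1) * fs / length(v)
    f <- pmin(f, fs - f)
    sum(s[f < 1])
  }
  expect_lt(lf_energy(out), 0.1 * lf_energy(x))      # >= 90% reduction
  expect_lt(abs(mean(out)), abs(mean(x)))
  # residual = 0 leaves the signal untouched
  dec0 <- dec; dec0$residual <- numeric(length(x))
  expect_identical(detrend(x, dec0), x)
})

test_that("normalization maps onto [0, 1] and rejects constants", {
  expect_equal(normalize01(c(2, 4, 6)), c(0, 0.5, 1))
  z <- runif(100)
  z[1] <- 0; z[2] <- 1
  expect_equal(normalize01(z), z)
  expect_error(normalize01(c(5, 5, 5)), "degenerate")
})

test_that("recording preprocessing composes the stages deterministically", {
  cfg <- small_config(n_cycles = 3L)
  oa <- vag_subject("OA01", "OA", 3, 60, "M", 1.75, 95)
  rec <- generate_recording(oa, "OKC", cfg, seed = 31)
  pp1 <- preprocess_recording(rec, n_trials = 3, seed = 5)
  pp2 <- preprocess_recording(rec, n_trials = 3, seed = 5)
  expect_identical(pp1$signal, pp2$signal)
  expect_equal(range(pp1$signal), c(0, 1))
  expect_equal(length(pp1$cycles), 3)
  # idle-only recording surfaces the cycle-detection failure
  rec$encoder <- rep(90, length(rec$encoder))
  expect_error(suppressWarnings(preprocess_recording(rec, n_trials = 2)),
               "no movement cycles")
})
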