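#' Detect movement cycles from the encoder channel
#'
#' Slope-based segmentation: a full cycle is a descent of the knee angle from
#' the upper hard stop (>= `hi` degrees) down to the lower stop (<= `lo`
#' degrees) and back up to >= `hi`. Boundaries are mapped from the encoder
#' clock onto acoustic sample indices. Idle samples before and after the
#' movement are excluded.
#'
#' @param encoder numeric vector of knee angles in degrees, within [0, 90].
#' @param fs_encoder,fs_acoustic sampling rates (Hz).
#' @param hi,lo angle thresholds (degrees) marking the top and bottom of an
#'   excursion.
#' @return data.frame with one row per detected cycle: `start`, `end`
#'   (1-based, half-open `[start, end)` acoustic sample indices),
#'   `start_time`, `end_time` (s). Zero rows (with a warning) when no motion
#'   is detected.
#' @export
detect_cycles <- function(encoder, fs_encoder, fs_acoustic, hi = 85, lo = 5) {
  stopifnot(all(encoder >= 0 - 1e-9), all(encoder <= 90 + 1e-9))
  n <- length(encoder)
  above <- which(encoder >= hi)
  below <- which(encoder <= lo)
  segs <- list()
  pos <- 1L
  repeat {
    bot <- below[below >= pos]
    if (length(bot) == 0) break
    bot <- bot[1]
    st <- above[above < bot]
    if (length(st) == 0) break
    st <- st[length(st)]
    en <- above[above > bot]
    if (length(en) == 0) break          # incomplete final cycle: discard
    en <- en[1]
    # refine each boundary to its local angle peak (the true turning point
    # sits at/above the hi threshold; climb while the angle keeps rising)
    while (st > 1L && encoder[st - 1L] > encoder[st]) st <- st - 1L
    while (en < n && encoder[en + 1L] > encoder[en]) en <- en + 1L
    segs[[length(segs) + 1L]] <- c(st, en)
    pos <- en
  }
  if (length(segs) == 0) {
    warning("no movement cycles detected in encoder trace")
    return(data.frame(start = integer(0), end = integer(0),
                      start_time = numeric(0), end_time = numeric(0)))
  }
  m <- do.call(rbind, segs)
  start_time <- (m[, 1] - 1) / fs_encoder
  end_time <- (m[, 2] - 1) / fs_encoder
  data.frame(start = floor(start_time * fs_acoustic) + 1L,
             end = floor(end_time * fs_acoustic) + 1L,
             start_time = start_time, end_time = end_time)
}

#' One sifting step
#'
#' Builds the upper and lower envelopes of `x` by natural cubic spline
#' interpolation through the local maxima and minima (mirror-extended at the
#' ends), takes their pointwise mean `m1 = (e_up + e_dow) / 2`, and returns
#' the proto-IMF `d1 = x - m1` together with the remainder `h1 = x - d1`.
#'
#' @param x numeric signal with at least two maxima and two minima.
#' @return list of class `vag_sift`: `x`, `e_up`, `e_dow`, `m1`, `d1`, `h1`,
#'   `n_max`, `n_min`.
#' @export
sift_once <- function(x) {
  env <- cpp_envelopes(as.numeric(x))
  if (!env$ok)
    stop("signal is monotone/trend-like: fewer than two maxima or two minima")
  m1 <- (env$e_up + env$e_dow) / 2
  d1 <- x - m1
  structure(list(x = x, e_up = env$e_up, e_dow = env$e_dow,
                 m1 = m1, d1 = d1, h1 = x - d1,
                 n_max = env$n_max, n_min = env$n_min),
            class = "vag_sift")
}

#' Extract one intrinsic mode function
#'
#' Iterates [sift_once()] on `x` until the Cauchy stopping criterion
#' `SD = sum((d_prev - d_cur)^2) / sum(d_prev^2) < sd_tol` is met together
#' with IMF admissibility (the number of extrema and of zero-crossings differ
#' by at most one), or `max_sift` iterations are reached (in which case the
#' current candidate is returned with a warning).
#'
#' @param x numeric signal.
#' @param sd_tol Cauchy criterion tolerance (default 0.2).
#' @param max_sift sift iteration cap per IMF (default 20; generous enough
#'   that candidates virtually always satisfy admissibility before the cap).
#' @return list: `imf`, `remainder` (= `x - imf`), `n_sift`, `converged`.
#' @export
extract_imf <- function(x, sd_tol = 0.2, max_sift = 20L) {
  res <- cpp_extract_imf(as.numeric(x), sd_tol, as.integer(max_sift))
  if (!res$siftable)
    stop("signal is monotone/trend-like: fewer than two maxima or two minima")
  if (!res$converged)
    warning("max sift iterations reached before the stopping criterion")
  list(imf = res$imf, remainder = x - res$imf,
       n_sift = res$n_sift, converged = res$converged)
}

#' Empirical mode decomposition
#'
#' Repeatedly extracts IMFs from the running remainder until it is
#' monotone/trend-like (fewer than two maxima or two minima) or `max_imf`
#' components have been peeled off. The remainder is the residual trend
#' `r(t)`. By telescoping, `rowSums(imfs) + residual` reproduces the input to
#' machine precision.
#'
#' @param x numeric signal (length >= 8).
#' @param sd_tol,max_sift sifting controls, see [extract_imf()].
#' @param max_imf IMF count cap; default `floor(log2(length(x)))`.
#' @return object of class `vag_imfset`: `input`, `imfs` (matrix, one column
#'   per IMF ordered highest frequency first), `residual`.
#' @export
emd <- function(x, sd_tol = 0.2, max_sift = 20L,
                max_imf = floor(log2(length(x)))) {
  x <- as.numeric(x)
  if (length(x) < 8) stop("signal too short for EMD (need length >= 8)")
  res <- suppressWarnings(
    cpp_emd(x, sd_tol, as.integer(max_sift), as.integer(max_imf)))
  structure(list(input = x, imfs = res$imfs, residual = res$residual),
            class = "vag_imfset")
}

#' @export
print.vag_imfset <- function(x, ...) {
  cat(sprintf("<vag_imfset> %d samples, %d IMFs + residual\n",
              length(x$input), ncol(x$imfs)))
  invisible(x)
}

#' Ensemble empirical mode decomposition
#'
#' Runs [emd()] on `n_trials` noise-assisted copies `y_n = x + w_n`, where
#' `w_n` is Gaussian white noise with standard deviation
#' `noise_std * sd(x)`, and averages the aligned IMFs and residuals across
#' the ensemble. Trials yielding fewer IMFs than the ensemble maximum are
#' padded with zero IMFs before averaging. Deterministic given `seed`
#' (trial `k` uses seed `seed + k`).
#'
#' @param x numeric signal.
#' @param noise_std added-noise standard deviation as a fraction of `sd(x)`
#'   (default 0.2).
#' @param n_trials ensemble size (default 100).
#' @param seed integer seed.
#' @param sd_tol,max_sift,max_imf passed to [emd()].
#' @return object of class `vag_imfset` holding the ensemble-mean IMFs and
#'   residual.
#' @export
eemd <- function(x, noise_std = 0.2, n_trials = 100L, seed = 1L,
                 sd_tol = 0.2, max_sift = 20L,
                 max_imf = floor(log2(length(x)))) {
  x <- as.numeric(x)
  if (n_trials < 1) stop("n_trials must be >= 1")
  if (noise_std <= 0) stop("noise_std must be > 0")
  sdx <- sd(x)
  sigma <- noise_std * if (sdx > 0) sdx else 1
  n <- length(x)
  trials <- vector("list", n_trials)
  for (k in seq_len(n_trials)) {
    set.seed(seed + k)
    y <- x + rnorm(n, 0, sigma)
    trials[[k]] <- suppressWarnings(
      cpp_emd(y, sd_tol, as.integer(max_sift), as.integer(max_imf)))
  }
  k_max <- max(vapply(trials, function(tr) ncol(tr$imfs), integer(1)))
  imfs <- matrix(0, n, k_max)
  residual <- numeric(n)
  for (tr in trials) {
    k_tr <- ncol(tr$imfs)
    if (k_tr > 0) imfs[, seq_len(k_tr)] <- imfs[, seq_len(k_tr)] + tr$imfs
    residual <- residual + tr$residual
  }
  structure(list(input = x, imfs = imfs / n_trials,
                 residual = residual / n_trials),
            class = "vag_imfset")
}

#' Remove the residual trend from a signal
#'
#' Sensor drift accumulates in the EMD residual `r(t)`; detrending subtracts
#' it from the input: `x - residual`.
#'
#' @param x numeric signal.
#' @param decomp a `vag_imfset` computed from `x` (or its noise ensemble).
#' @return detrended signal.
#' @export
detrend <- function(x, decomp) {
  stopifnot(inherits(decomp, "vag_imfset"), length(x) == length(decomp$residual))
  as.numeric(x) - decomp$residual
}

#' Normalize a signal to [0, 1]
#'
#' `(x - min) / (max - min)`. Constant signals have no amplitude range and
#' are rejected.
#'
#' @param x numeric signal.
#' @return rescaled signal with `min = 0`, `max = 1`.
#' @export
normalize01 <- function(x) {
  r <- range(x)
  if (r[1] == r[2]) stop("degenerate amplitude range: constant signal")
  (x - r[1]) / (r[2] - r[1])
}

#' Preprocess a recording end-to-end
#'
#' Applies the full cleaning chain in order: movement-cycle cutting by encoder
#' slope detection, EEMD on the motion region of the acoustic channel,
#' residual-trend removal, and [0, 1] normalization. EEMD is run once per
#' recording (on the idle-trimmed signal) rather than per cycle; longer
#' signals stabilize the decomposition, and the cycle boundaries are applied
#' to the cleaned signal afterwards.
#'
#' @param rec a [generate_recording()] / [read_recording()] object.
#' @param noise_std,n_trials,seed EEMD controls, see [eemd()].
#' @param ... further arguments to [eemd()].
#' @return list: `signal` (cleaned, normalized motion-region signal),
#'   `cycles` (list of per-cycle slices of `signal`), `segments` (the
#'   [detect_cycles()] table), `n_imfs`, and `motion` (acoustic index range
#'   used).
#' @export
preprocess_recording <- function(rec, noise_std = 0.2, n_trials = 100L,
                                 seed = 1L, ...) {
  stopifnot(inherits(rec, "vag_recording"))
  segs <- detect_cycles(rec$encoder, rec$fs_encoder, rec$fs_acoustic)
  if (nrow(segs) == 0)
    stop("no movement cycles detected in recording (stage: detect_cycles)")
  lo <- min(segs$start)
  hi <- min(max(segs$end) - 1L, length(rec$acoustic))
  x <- as.numeric(rec$acoustic[lo:hi])
  decomp <- eemd(x, noise_std = noise_std, n_trials = n_trials, seed = seed, ...)
  cleaned <- normalize01(detrend(x, decomp))
  cyc <- lapply(seq_len(nrow(segs)), function(k) {
    i0 <- segs$start[k] - lo + 1L
    i1 <- min(segs$end[k] - lo, length(cleaned))
    cleaned[i0:i1]
  })
  list(signal = cleaned, cycles = cyc, segments = segs,
       n_imfs = ncol(decomp$imfs), motion = c(lo, hi))
}
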