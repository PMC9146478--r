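#' Generator configuration for a synthetic VAG cohort
#'
#' Bundles the acquisition geometry and the statistical structure of the
#' simulated recordings. Defaults mirror the acquisition protocol the pipeline
#' is designed for: a solid-body microphone on the patella sampled at 1400 Hz
#' with a 10-bit ADC, a 10 Hz knee-angle encoder hard-stopped at 0 and 90
#' degrees, ten 90-0-90 degree movement cycles of roughly 2 s each, and a
#' cohort of 33 healthy controls (HC) and 34 osteoarthritis (OA) subjects.
#'
#' Amplitudes are expressed relative to the background-noise standard
#' deviation (`noise_std = 1` is the base unit). Burst rate and amplitude are
#' indexed by ICRS cartilage-lesion grade 0-4 (grade 0 = healthy) and must be
#' non-decreasing in grade, so that expected transient energy grows with
#' lesion severity.
#'
#' @param n_hc,n_oa number of healthy-control / osteoarthritis subjects.
#' @param seed integer seed controlling subject sampling and recording noise.
#' @param fs_acoustic acoustic sampling rate (Hz).
#' @param fs_encoder encoder sampling rate (Hz).
#' @param n_cycles movement cycles per recording.
#' @param cycle_period nominal cycle duration (s).
#' @param quant_bits ADC resolution (bits).
#' @param burst_rate_per_grade expected transient bursts per cycle, grades 0-4.
#' @param burst_amp_per_grade burst amplitude (relative), grades 0-4.
#' @param drift_amp sensor-drift amplitude (relative).
#' @param noise_std background noise standard deviation (base unit).
#' @param hum_amp 50 Hz mains-hum amplitude (relative); 0 disables.
#' @param friction_amp amplitude of the angular-velocity-tracking friction
#'   noise (relative).
#' @param jitter_frac per-cycle duration jitter as a fraction of
#'   `cycle_period`.
#' @param idle_pad idle time (s) at 90 degrees before and after the movement,
#'   so slope detection has something to cut.
#' @param knees_per_hc recordings per chain for each HC subject (the reference
#'   protocol records both knees of controls but only the operated knee of
#'   patients).
#' @param grade_levels ICRS grades sampled for OA subjects. The default `2:4`
#'   emulates a surgical cohort dominated by established lesions.
#' @param full_scale ADC full-scale amplitude (relative units); samples are
#'   clipped, then quantized onto `2^quant_bits` levels.
#' @return an object of class `vag_config`.
#' @export
vag_config <- function(n_hc = 33L, n_oa = 34L, seed = 1L,
                       fs_acoustic = 1400, fs_encoder = 10,
                       n_cycles = 10L, cycle_period = 2.0, quant_bits = 10L,
                       burst_rate_per_grade = c(0.2, 1, 2, 4, 6),
                       burst_amp_per_grade = c(0.5, 2, 4, 6, 8),
                       drift_amp = 1.5, noise_std = 1.0, hum_amp = 0.1,
                       friction_amp = 0.8, jitter_frac = 0.1, idle_pad = 1.0,
                       knees_per_hc = 2L, grade_levels = 2:4,
                       full_scale = 12) {
  stopifnot(n_cycles >= 1, fs_acoustic > 0, fs_encoder > 0,
            cycle_period > 0, quant_bits >= 2, noise_std >= 0,
            length(burst_rate_per_grade) == 5, length(burst_amp_per_grade) == 5,
            all(diff(burst_rate_per_grade) >= 0),
            all(grade_levels %in% 1:4), full_scale > 0,
            jitter_frac >= 0, jitter_frac < 1)
  # highest generated component: band-limited noise up to 600 Hz (see
  # generate_recording); the acoustic rate must oversample it
  if (fs_acoustic <= 2 * 600)
    stop("fs_acoustic must exceed twice the highest generated frequency (600 Hz)")
  structure(list(
    n_hc = as.integer(n_hc), n_oa = as.integer(n_oa), seed = as.integer(seed),
    fs_acoustic = fs_acoustic, fs_encoder = fs_encoder,
    n_cycles = as.integer(n_cycles), cycle_period = cycle_period,
    quant_bits = as.integer(quant_bits),
    burst_rate_per_grade = burst_rate_per_grade,
    burst_amp_per_grade = burst_amp_per_grade,
    drift_amp = drift_amp, noise_std = noise_std, hum_amp = hum_amp,
    friction_amp = friction_amp, jitter_frac = jitter_frac,
    idle_pad = idle_pad, knees_per_hc = as.integer(knees_per_hc),
    grade_levels = as.integer(grade_levels), full_scale = full_scale
  ), class = "vag_config")
}

#' Construct a subject profile
#'
#' @param subject_id opaque identifier.
#' @param group `"HC"` or `"OA"`.
#' @param icrs_grade ICRS cartilage-lesion grade: 0 for HC, 1-4 for OA.
#' @param age years. @param sex `"M"` or `"F"`.
#' @param height metres. @param weight kilograms.
#' @return an object of class `vag_subject`; BMI is derived as
#'   weight / height^2.
#' @export
vag_subject <- function(subject_id, group, icrs_grade, age, sex, height, weight) {
  group <- match.arg(group, c("HC", "OA"))
  icrs_grade <- as.integer(icrs_grade)
  if (group == "HC" && icrs_grade != 0L)
    stop("HC subjects must have icrs_grade 0")
  if (group == "OA" && !icrs_grade %in% 1:4)
    stop("OA subjects must have icrs_grade in 1..4")
  sex <- match.arg(sex, c("M", "F"))
  stopifnot(age > 0, height > 0, weight > 0)
  structure(list(subject_id = as.character(subject_id), group = group,
                 icrs_grade = icrs_grade, age = age, sex = sex,
                 height = height, weight = weight,
                 bmi = weight / height^2),
            class = "vag_subject")
}

# Per-group demographic distributions of the reference clinical cohort
# (mean, sd): age in years, height in m, weight in kg, and P(male).
.demographics <- list(
  HC = list(age = c(24.10, 5.56), height = c(1.71, 0.09),
            weight = c(65.16, 15.10), p_male = 9 / 33),
  OA = list(age = c(56.15, 12.99), height = c(1.69, 0.09),
            weight = c(89.08, 14.30), p_male = 15 / 34)
)

#' Sample subject profiles for a synthetic cohort
#'
#' Demographics are drawn from per-group normal distributions matching the
#' reference clinical cohort (HC age 24.10 +/- 5.56 y, OA 56.15 +/- 12.99 y,
#' etc.); BMI is derived from the sampled height and weight. OA lesion grades
#' are drawn uniformly from `config$grade_levels`. Sex is carried only as a
#' covariate; it affects no acoustic parameter.
#'
#' @param config a [vag_config()].
#' @return a list of `vag_subject` objects (HC first, then OA).
#' @export
sample_subjects <- function(config) {
  stopifnot(inherits(config, "vag_config"))
  if (config$n_hc < 1 || config$n_oa < 1)
    stop("n_hc and n_oa must both be >= 1")
  set.seed(config$seed)
  draw <- function(group, i) {
    d <- .demographics[[group]]
    age <- max(18, rnorm(1, d$age[1], d$age[2]))
    height <- max(1.4, rnorm(1, d$height[1], d$height[2]))
    weight <- max(40, rnorm(1, d$weight[1], d$weight[2]))
    sex <- if (runif(1) < d$p_male) "M" else "F"
    grade <- if (group == "HC") 0L else
      config$grade_levels[sample.int(length(config$grade_levels), 1)]
    vag_subject(sprintf("%s%02d", group, i), group, grade, age, sex,
                height, weight)
  }
  c(lapply(seq_len(config$n_hc), function(i) draw("HC", i)),
    lapply(seq_len(config$n_oa), function(i) draw("OA", i)))
}

#' Generate a knee-angle encoder trace
#'
#' Produces `n_cycles` smooth 90-0-90 degree excursions (raised-cosine
#' profile), each lasting `cycle_period * (1 + u)` seconds with
#' `u ~ U(-jitter_frac, jitter_frac)`, padded with `idle_pad` seconds of rest
#' at 90 degrees on both sides. Hard stops clip the trace to [0, 90].
#'
#' @param config a [vag_config()].
#' @param jitter_seed integer seed for the per-cycle duration jitter.
#' @return numeric vector of angles (degrees) with attributes
#'   `cycles` (data.frame of ground-truth `start_time`/`end_time` in s) and
#'   `fs` (encoder rate, Hz).
#' @export
generate_encoder_trace <- function(config, jitter_seed = config$seed) {
  stopifnot(inherits(config, "vag_config"))
  set.seed(jitter_seed)
  durations <- config$cycle_period *
    (1 + runif(config$n_cycles, -config$jitter_frac, config$jitter_frac))
  starts <- config$idle_pad + c(0, cumsum(durations[-config$n_cycles]))
  ends <- starts + durations
  total <- ends[config$n_cycles] + config$idle_pad
  tt <- seq(0, total, by = 1 / config$fs_encoder)
  angle <- rep(90, length(tt))
  for (k in seq_len(config$n_cycles)) {
    in_k <- tt >= starts[k] & tt < ends[k]
    angle[in_k] <- 45 + 45 * cos(2 * pi * (tt[in_k] - starts[k]) / durations[k])
  }
  angle <- pmin(90, pmax(0, angle))
  structure(angle,
            cycles = data.frame(start_time = starts, end_time = ends),
            fs = config$fs_encoder)
}

# Band-limited Gaussian noise by FFT masking: white noise with all Fourier
# components outside [f_lo, f_hi] zeroed, rescaled to unit sd.
.bandlimited_noise <- function(n, fs, f_lo, f_hi) {
  w <- rnorm(n)
  spec <- fft(w)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)                     # two-sided frequency axis
  spec[f < f_lo | f > f_hi] <- 0
  out <- Re(fft(spec, inverse = TRUE)) / n
  s <- sd(out)
  if (s > 0) out / s else out
}

#' Generate one synthetic VAG recording
#'
#' The acoustic channel is assembled from: (i) background band-limited
#' Gaussian noise (10-600 Hz), (ii) a friction term whose envelope tracks the
#' absolute angular velocity of the knee, (iii) Poisson-placed exponentially
#' damped sinusoid bursts (50-400 Hz carrier, 10-30 ms decay) whose rate and
#' amplitude grow with the subject's ICRS grade -- the "click" morphology of a
#' damaged cartilage surface, (iv) slow sensor drift (integrated noise,
#' low-passed below 0.5 Hz), and (v) optional 50 Hz mains hum. The sum is
#' clipped at `full_scale` and quantized onto `2^quant_bits` ADC levels.
#'
#' The kinetic chain shapes the friction envelope: in the closed chain (CKC,
#' sit-to-stand) both flexion and extension are loaded equally, while in the
#' open chain (OKC, free-hanging extension) the extension phase dominates.
#'
#' @param subject a [vag_subject()].
#' @param chain `"OKC"` or `"CKC"`.
#' @param config a [vag_config()].
#' @param seed integer; the recording is deterministic given
#'   `(seed, subject, chain)`.
#' @return an object of class `vag_recording`: quantized acoustic samples
#'   (integer ADC counts), encoder angles, sampling rates, the subject, the
#'   chain, the ground-truth cycle table, and a `burst_log` data.frame
#'   (time, freq, amp, cycle) of every injected transient.
#' @export
generate_recording <- function(subject, chain, config, seed = config$seed) {
  stopifnot(inherits(subject, "vag_subject"), inherits(config, "vag_config"))
  chain <- match.arg(chain, c("OKC", "CKC"))
  grade <- subject$icrs_grade
  if (!grade %in% 0:4) stop("invalid ICRS grade: ", grade)

  encoder <- generate_encoder_trace(config, jitter_seed = seed)
  cycles <- attr(encoder, "cycles")
  total <- length(encoder) / config$fs_encoder
  n <- round(total * config$fs_acoustic)
  tt <- (seq_len(n) - 1) / config$fs_acoustic

  set.seed(seed + 1L)
  fs <- config$fs_acoustic
  x <- config$noise_std * .bandlimited_noise(n, fs, 10, 600)

  # friction: envelope proportional to |d(angle)/dt|, chain-weighted
  omega <- numeric(n)
  weight <- numeric(n)
  for (k in seq_len(nrow(cycles))) {
    Tk <- cycles$end_time[k] - cycles$start_time[k]
    in_k <- tt >= cycles$start_time[k] & tt < cycles$end_time[k]
    ph <- 2 * pi * (tt[in_k] - cycles$start_time[k]) / Tk
    dtheta <- -45 * (2 * pi / Tk) * sin(ph)          # deg/s
    omega[in_k] <- abs(dtheta)
    weight[in_k] <- if (chain == "CKC") 1 else ifelse(dtheta < 0, 1.5, 0.5)
  }
  env <- omega * weight
  if (max(env) > 0) env <- env / max(env)
  x <- x + config$friction_amp * env * .bandlimited_noise(n, fs, 30, 400)

  # severity-dependent transient bursts, Poisson-placed per cycle
  rate <- config$burst_rate_per_grade[grade + 1L]
  amp0 <- config$burst_amp_per_grade[grade + 1L]
  burst_log <- data.frame(time = numeric(0), freq = numeric(0),
                          amp = numeric(0), cycle = integer(0))
  if (rate > 0) {
    for (k in seq_len(nrow(cycles))) {
      n_b <- stats::rpois(1, rate)
      if (n_b == 0) next
      t0 <- runif(n_b, cycles$start_time[k], cycles$end_time[k] - 0.05)
      fb <- runif(n_b, 50, 400)
      tau <- runif(n_b, 0.010, 0.030)
      ab <- amp0 * runif(n_b, 0.8, 1.2)
      for (b in seq_len(n_b)) {
        idx <- which(tt >= t0[b] & tt <= t0[b] + 5 * tau[b])
        s <- tt[idx] - t0[b]
        x[idx] <- x[idx] + ab[b] * exp(-s / tau[b]) * sin(2 * pi * fb[b] * s)
      }
      burst_log <- rbind(burst_log,
                         data.frame(time = t0, freq = fb, amp = ab, cycle = k))
    }
  }

  # sensor drift: integrated white noise, low-passed (< 0.5 Hz), then scaled
  if (config$drift_amp > 0) {
    d0 <- cumsum(rnorm(n))
    spec <- fft(d0)
    f <- (seq_len(n) - 1) * fs / n
    f <- pmin(f, fs - f)
    spec[f > 0.5] <- 0
    drift <- Re(fft(spec, inverse = TRUE)) / n
    s <- sd(drift)
    if (s > 0) x <- x + config$drift_amp * (drift - mean(drift)) / s
  }

  if (config$hum_amp > 0)
    x <- x + config$hum_amp * sin(2 * pi * 50 * tt + runif(1, 0, 2 * pi))

  # 10-bit ADC: clip to +/- full_scale, quantize to integer counts
  levels <- 2L^config$quant_bits - 1L
  fsc <- config$full_scale
  counts <- as.integer(round((pmin(fsc, pmax(-fsc, x)) + fsc) / (2 * fsc) * levels))

  structure(list(subject = subject, chain = chain,
                 acoustic = counts, encoder = as.numeric(encoder),
                 fs_acoustic = config$fs_acoustic,
                 fs_encoder = config$fs_encoder,
                 quant_bits = config$quant_bits,
                 full_scale = config$full_scale,
                 cycles = cycles, burst_log = burst_log),
            class = "vag_recording")
}

#' @export
print.vag_recording <- function(x, ...) {
  cat(sprintf("<vag_recording> %s (%s, ICRS %d) chain=%s: %d acoustic samples @ %g Hz, %d encoder samples @ %g Hz, %d bursts\n",
              x$subject$subject_id, x$subject$group, x$subject$icrs_grade,
              x$chain, length(x$acoustic), x$fs_acoustic,
              length(x$encoder), x$fs_encoder, nrow(x$burst_log)))
  invisible(x)
}

#' Generate a full synthetic cohort
#'
#' Samples `n_hc + n_oa` subject profiles and generates recordings in both
#' kinetic chains: `knees_per_hc` recordings per chain for each control
#' (default 2, both knees) and one per chain for each OA subject. Everything
#' is deterministic given `config` (recording seeds fan out from
#' `config$seed` by a fixed counter).
#'
#' @param config a [vag_config()].
#' @param chains which kinetic chains to generate (default both).
#' @return a list with `recordings` (list of [generate_recording()] outputs),
#'   `subjects` (data.frame of profiles), and `manifest` (one row per
#'   recording: subject_id, group, grade, age, sex, bmi, chain, knee, seed).
#' @export
generate_cohort <- function(config, chains = c("OKC", "CKC")) {
  stopifnot(inherits(config, "vag_config"))
  chains <- match.arg(chains, c("OKC", "CKC"), several.ok = TRUE)
  subjects <- sample_subjects(config)
  recordings <- list()
  manifest <- list()
  counter <- 0L
  for (s in subjects) {
    n_knee <- if (s$group == "HC") config$knees_per_hc else 1L
    for (knee in seq_len(n_knee)) {
      for (ch in chains) {
        counter <- counter + 1L
        rec_seed <- config$seed + 1000L * counter
        rec <- generate_recording(s, ch, config, seed = rec_seed)
        rec$knee <- knee
        recordings[[length(recordings) + 1L]] <- rec
        manifest[[length(manifest) + 1L]] <- data.frame(
          subject_id = s$subject_id, group = s$group, grade = s$icrs_grade,
          age = s$age, sex = s$sex, bmi = s$bmi, chain = ch, knee = knee,
          seed = rec_seed)
      }
    }
  }
  subj_df <- do.call(rbind, lapply(subjects, function(s)
    data.frame(subject_id = s$subject_id, group = s$group,
               icrs_grade = s$icrs_grade, age = s$age, sex = s$sex,
               height = s$height, weight = s$weight, bmi = s$bmi)))
  list(recordings = recordings, subjects = subj_df,
       manifest = do.call(rbind, manifest))
}
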