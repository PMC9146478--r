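#' Names of the twelve time-domain signal measures, in canonical order
#' @export
vag_feature_names <- function() {
  c("mv", "sa", "rms", "pv", "ppv", "cf", "if", "sf",
    "var", "kur", "m6a", "m8a")
}

#' Extract the twelve time-domain signal measures
#'
#' Computes, for a cleaned signal `x` of length `N`:
#' \describe{
#'   \item{mv}{mean value, `sum(x)/N`}
#'   \item{sa}{straightened (rectified) average, `sum(|x|)/N`}
#'   \item{rms}{root mean square, `sqrt(sum(x^2)/N)`}
#'   \item{pv}{peak value, `max(|x|)`}
#'   \item{ppv}{peak-to-peak value, `|max(x) - min(x)|`}
#'   \item{cf}{crest factor, `pv / rms`}
#'   \item{if}{impact (impulsivity) factor, `pv / mv`}
#'   \item{sf}{shape factor, `rms / sa` (on a [0, 1]-normalized signal the
#'     rectified average equals the mean, so this coincides with `rms / mv`)}
#'   \item{var}{sample variance with the `1/(N-1)` convention}
#'   \item{kur}{kurtosis: fourth `1/N` central moment over the squared
#'     second `1/N` central moment}
#'   \item{m6a}{sixth `1/N` central moment over the cubed second}
#'   \item{m8a}{eighth `1/N` central moment over the fourth power of the
#'     second}
#' }
#' The biased (`1/N`) central moments in kur/m6a/m8a and the unbiased
#' variance are deliberate mixed conventions, matching the measure
#' definitions used in vibroacoustic condition monitoring.
#'
#' Ratio measures with a vanishing denominator are an upstream-bug signal on
#' normalized data and raise an error (condition class
#' `vagdx_undefined_feature`) rather than returning a sentinel.
#'
#' @param x numeric signal, length >= 2.
#' @return named numeric vector of the 12 measures with attribute
#'   `n_samples`.
#' @export
extract_features <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 2) stop("need at least 2 samples")
  mv <- mean(x)
  sa <- mean(abs(x))
  rms <- sqrt(mean(x^2))
  pv <- max(abs(x))
  ppv <- abs(max(x) - min(x))
  undef <- function(what)
    stop(structure(class = c("vagdx_undefined_feature", "error", "condition"),
                   list(message = paste0(what, " undefined (zero denominator)"),
                        call = sys.call(-1))))
  cf <- if (rms == 0) undef("crest factor") else pv / rms
  if_ <- if (mv == 0) undef("impact factor") else pv / mv
  sf <- if (sa == 0) undef("shape factor") else rms / sa
  v_unb <- sum((x - mv)^2) / (n - 1)
  m2 <- mean((x - mv)^2)
  if (m2 == 0) {
    kur <- m6a <- m8a <- undef("kurtosis/M6A/M8A")
  } else {
    kur <- mean((x - mv)^4) / m2^2
    m6a <- mean((x - mv)^6) / m2^3
    m8a <- mean((x - mv)^8) / m2^4
  }
  out <- c(mv = mv, sa = sa, rms = rms, pv = pv, ppv = ppv, cf = cf,
           "if" = if_, sf = sf, var = v_unb, kur = kur, m6a = m6a, m8a = m8a)
  attr(out, "n_samples") <- n
  out
}

#' Assemble a per-case record: signal measures plus demographic covariates
#'
#' @param features named vector from [extract_features()], or a named list of
#'   such vectors keyed by chain (for the both-chains variant each chain's
#'   block is kept as a separate case by the pipeline; this helper attaches
#'   covariates to one block).
#' @param subject a [vag_subject()].
#' @param chain `"OKC"` or `"CKC"`.
#' @return one-row data.frame: the 12 measures, `age`, `sex` (0 = F, 1 = M),
#'   `bmi`, `chain`, and binary `label` (`"HC"` or `"OA"`; all ICRS grades
#'   1-4 collapse to `"OA"`).
#' @export
build_case <- function(features, subject, chain) {
  stopifnot(inherits(subject, "vag_subject"))
  chain <- match.arg(chain, c("OKC", "CKC"))
  fn <- vag_feature_names()
  if (!all(fn %in% names(features)))
    stop("features must contain all 12 measures: missing ",
         paste(setdiff(fn, names(features)), collapse = ", "))
  for (cov in c("age", "sex", "bmi"))
    if (is.null(subject[[cov]])) stop("missing covariate: ", cov)
  df <- as.data.frame(as.list(features[fn]), check.names = FALSE)
  df$age <- subject$age
  df$sex <- as.integer(subject$sex == "M")
  df$bmi <- subject$bmi
  df$chain <- chain
  df$label <- if (subject$group == "HC") "HC" else "OA"
  df$subject_id <- subject$subject_id
  df
}
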