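#' Write a recording to CSV
#'
#' One file per recording: `#`-prefixed `key=value` metadata header lines
#' (acquisition parameters, subject fields, chain, and the raw encoder series),
#' then a column header, then one row per acoustic sample with the encoder
#' angle held (zero-order hold) on the acoustic clock. Comma delimiter, `.`
#' decimal, LF line endings, UTF-8; no timestamps, so writing the same
#' recording twice yields byte-identical files.
#'
#' @param rec a `vag_recording`.
#' @param path output file path; its directory must exist.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "vag_recording"))
  if (!dir.exists(dirname(path)))
    stop("cannot write recording: directory does not exist: ", dirname(path))
  s <- rec$subject
  meta <- c(
    fs_acoustic = rec$fs_acoustic, fs_encoder = rec$fs_encoder,
    quant_bits = rec$quant_bits, full_scale = rec$full_scale,
    subject_id = s$subject_id, group = s$group, icrs_grade = s$icrs_grade,
    age = sprintf("%.17g", s$age), sex = s$sex,
    height = sprintf("%.17g", s$height),
    weight = sprintf("%.17g", s$weight), chain = rec$chain,
    encoder_raw = paste(sprintf("%.17g", rec$encoder), collapse = ";"))
  hdr <- paste0("#", names(meta), "=", meta)
  n <- length(rec$acoustic)
  tt <- (seq_len(n) - 1) / rec$fs_acoustic
  enc_idx <- pmin(length(rec$encoder), floor(tt * rec$fs_encoder) + 1L)
  body <- paste(format(tt, digits = 12, trim = TRUE, scientific = FALSE),
                rec$acoustic,
                format(rec$encoder[enc_idx], digits = 12, trim = TRUE),
                sep = ",")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(hdr, "time,acoustic,encoder", body), con, sep = "\n",
             useBytes = TRUE)
  invisible(path)
}

#' Read a recording written by [write_recording()]
#'
#' @param path input file path.
#' @return a `vag_recording` (ground-truth generator fields `cycles` and
#'   `burst_log` are not serialized and come back empty).
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) stop("recording file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  is_meta <- startsWith(lines, "#")
  meta_lines <- sub("^#", "", lines[is_meta])
  kv <- regmatches(meta_lines, regexpr("=", meta_lines), invert = TRUE)
  meta <- setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  required <- c("fs_acoustic", "fs_encoder", "quant_bits", "subject_id",
                "group", "icrs_grade", "age", "sex", "height", "weight",
                "chain", "encoder_raw")
  missing <- setdiff(required, names(meta))
  if (length(missing))
    stop("missing required metadata key(s): ", paste(missing, collapse = ", "))
  body <- lines[!is_meta]
  if (length(body) < 2) stop("no data rows in ", path)
  body <- body[-1]                            # drop column header
  parts <- strsplit(body, ",", fixed = TRUE)
  bad <- which(lengths(parts) != 3)
  if (length(bad))
    stop("malformed data row(s) at line(s): ",
         paste(bad + sum(is_meta) + 1L, collapse = ", "))
  acoustic <- as.integer(vapply(parts, `[`, "", 2))
  subject <- vag_subject(meta[["subject_id"]], meta[["group"]],
                         as.integer(meta[["icrs_grade"]]),
                         as.numeric(meta[["age"]]), meta[["sex"]],
                         as.numeric(meta[["height"]]),
                         as.numeric(meta[["weight"]]))
  structure(list(subject = subject, chain = meta[["chain"]],
                 acoustic = acoustic,
                 encoder = as.numeric(strsplit(meta[["encoder_raw"]], ";",
                                               fixed = TRUE)[[1]]),
                 fs_acoustic = as.numeric(meta[["fs_acoustic"]]),
                 fs_encoder = as.numeric(meta[["fs_encoder"]]),
                 quant_bits = as.integer(meta[["quant_bits"]]),
                 full_scale = as.numeric(meta[["full_scale"]]),
                 cycles = NULL, burst_log = NULL),
            class = "vag_recording")
}

.feature_table_cols <- function() {
  c(vag_feature_names(), "age", "sex", "bmi", "chain", "label", "subject_id")
}

#' Write a feature table to CSV
#'
#' Fixed column order: the 12 signal measures in canonical order, then `age`,
#' `sex`, `bmi`, `chain`, `label`, `subject_id`. Numeric columns are written
#' with 15 significant digits (round-trip stable well beyond 12).
#'
#' @param cases data.frame of [build_case()] rows.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(cases, path) {
  cols <- .feature_table_cols()
  if (nrow(cases) > 0) {
    missing <- setdiff(cols, names(cases))
    if (length(missing)) stop("feature table missing columns: ",
                              paste(missing, collapse = ", "))
    cases <- cases[, cols]
  } else {
    cases <- as.data.frame(setNames(rep(list(numeric(0)), length(cols)), cols),
                           check.names = FALSE)
  }
  num <- vapply(cases, is.numeric, TRUE)
  cases[num] <- lapply(cases[num], function(v) format(v, digits = 15, trim = TRUE))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(paste(cols, collapse = ","),
               if (nrow(cases) > 0) do.call(paste, c(cases, sep = ","))),
             con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#' @param path input path.
#' @return data.frame with the canonical column order.
#' @export
read_feature_table <- function(path) {
  df <- read.csv(path, check.names = FALSE,
                 colClasses = setNames(
                   c(rep("numeric", 15), "character", "character", "character"),
                   .feature_table_cols()))
  df
}

#' Write an evaluation report as structured JSON text
#'
#' Serializes every field of an evaluation report (confusion counts, derived
#' metrics, ROC point list, AUC, operating threshold) with full numeric
#' precision and no timestamps, so writes are idempotent.
#'
#' @param report a list, typically from [evaluation_report()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a report written by [write_report()]
#' @param path input path.
#' @return the report list.
#' @export
read_report <- function(path) {
  jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
}
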