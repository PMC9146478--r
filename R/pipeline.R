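#' Pipeline configuration
#'
#' Bundles every stage's parameters for an end-to-end run. The master `seed`
#' fans out to per-stage seeds by a fixed counter scheme (cohort = seed,
#' EEMD = seed + 10000 + recording index, split = seed + 1, NCA = seed + 2,
#' network training = seed + 3), so a single knob reproduces the whole run.
#'
#' @param variant `"I"` (open kinetic chain), `"II"` (closed chain), or
#'   `"III"` (both chains, stacked as separate cases with a chain-indicator
#'   input).
#' @param cohort a [vag_config()].
#' @param eemd list: `noise_std`, `n_trials` (see [eemd()]).
#' @param nca list: `sigma`, `lambda_grid`, `n_folds`, `threshold_frac`.
#' @param split list: `fractions`, `stratified`.
#' @param hidden_grid_mlp,hidden_grid_rbf hidden-layer sizes searched per
#'   family.
#' @param max_iter network training iteration cap.
#' @param output_dir optional directory for artifacts (feature table, weight
#'   table, leaderboards, reports, manifest).
#' @param seed master seed.
#' @return object of class `vag_pipeline_config`.
#' @export
pipeline_config <- function(variant = c("I", "II", "III"),
                            cohort = vag_config(),
                            eemd = list(noise_std = 0.2, n_trials = 100L),
                            nca = list(sigma = 1, lambda_grid = NULL,
                                       n_folds = 5L, threshold_frac = 0.05),
                            split = list(fractions = c(train = 0.70,
                                                       test = 0.15,
                                                       validation = 0.15),
                                         stratified = TRUE),
                            hidden_grid_mlp = c(8, 16),
                            hidden_grid_rbf = c(14, 35),
                            max_iter = 100L,
                            output_dir = NULL, seed = 1L) {
  variant <- match.arg(variant)
  stopifnot(inherits(cohort, "vag_config"))
  structure(list(variant = variant, cohort = cohort, eemd = eemd, nca = nca,
                 split = split, hidden_grid_mlp = hidden_grid_mlp,
                 hidden_grid_rbf = hidden_grid_rbf,
                 max_iter = as.integer(max_iter),
                 output_dir = output_dir, seed = as.integer(seed)),
            class = "vag_pipeline_config")
}

.variant_chains <- function(variant)
  switch(variant, I = "OKC", II = "CKC", III = c("OKC", "CKC"))

#' Build the per-case feature table for a cohort
#'
#' Preprocesses every recording ([preprocess_recording()]), extracts the 12
#' signal measures from the concatenation of its cleaned movement cycles, and
#' attaches the demographic covariates ([build_case()]). In the both-chains
#' variant each chain's recording is a separate case.
#'
#' @param cohort output of [generate_cohort()] (or a list of recordings under
#'   `$recordings`).
#' @param eemd list of EEMD controls (`noise_std`, `n_trials`).
#' @param seed master seed (per-recording EEMD seeds are
#'   `seed + 10000 + index`).
#' @return data.frame of cases in the canonical feature-table column order.
#' @export
cohort_feature_table <- function(cohort, eemd = list(noise_std = 0.2,
                                                     n_trials = 100L),
                                 seed = 1L) {
  rows <- lapply(seq_along(cohort$recordings), function(i) {
    rec <- cohort$recordings[[i]]
    pp <- tryCatch(
      preprocess_recording(rec, noise_std = eemd$noise_std,
                           n_trials = eemd$n_trials,
                           seed = seed + 10000L + i),
      error = function(e) stop("preprocess failed for recording ", i, " (",
                               rec$subject$subject_id, "/", rec$chain, "): ",
                               conditionMessage(e)))
    feats <- extract_features(unlist(pp$cycles, use.names = FALSE))
    build_case(feats, rec$subject, rec$chain)
  })
  do.call(rbind, rows)
}

#' Run one classification variant end to end
#'
#' Executes the full chain: synthetic-cohort generation (for the variant's
#' kinetic chain(s)) -> preprocessing -> feature extraction -> NCA feature
#' selection over the 12 signal measures -> stratified 70/15/15 split ->
#' model search for both network families -> test-set evaluation. The
#' classifier inputs are the NCA-selected measures plus age, sex and BMI
#' (plus a chain indicator in variant III). Fully deterministic given the
#' configuration.
#'
#' @param cfg a [pipeline_config()].
#' @return list of class `vag_run`: `feature_table`, `nca` model,
#'   `selected_features`, `split`, per-family `search` results, `reports`
#'   (test-set [evaluation_report()] per family), and `manifest`.
#' @export
run_variant <- function(cfg) {
  stopifnot(inherits(cfg, "vag_pipeline_config"))
  chains <- .variant_chains(cfg$variant)
  cohort <- generate_cohort(cfg$cohort, chains = chains)
  cases <- cohort_feature_table(cohort, cfg$eemd, seed = cfg$seed)

  fn <- vag_feature_names()
  X12 <- as.matrix(cases[, fn])
  labels <- cases$label
  nca <- fit_nca(X12, labels, sigma = cfg$nca$sigma,
                 lambda_grid = cfg$nca$lambda_grid,
                 n_folds = cfg$nca$n_folds, seed = cfg$seed + 2L,
                 threshold_frac = cfg$nca$threshold_frac)
  sel <- fn[nca$selected]

  Xcls <- as.matrix(cbind(cases[, sel, drop = FALSE],
                          age = cases$age, sex = cases$sex, bmi = cases$bmi))
  if (cfg$variant == "III")
    Xcls <- cbind(Xcls, chain_okc = as.integer(cases$chain == "OKC"))

  split <- split_dataset(labels, fractions = cfg$split$fractions,
                         seed = cfg$seed + 1L,
                         stratified = isTRUE(cfg$split$stratified))
  searches <- list(
    MLP = model_search(Xcls, labels, split, "MLP",
                       hidden_grid = cfg$hidden_grid_mlp,
                       seed = cfg$seed + 3L, max_iter = cfg$max_iter),
    RBF = model_search(Xcls, labels, split, "RBF",
                       hidden_grid = cfg$hidden_grid_rbf,
                       seed = cfg$seed + 3L, max_iter = cfg$max_iter))
  reports <- lapply(searches, function(s) {
    P <- predict_proba(s$best, Xcls[split$test, , drop = FALSE])
    evaluation_report(labels[split$test], P[, "OA"],
                      predictions = predict_class(s$best,
                                                  Xcls[split$test, , drop = FALSE]))
  })
  manifest <- list(variant = cfg$variant, seed = cfg$seed,
                   n_cases = nrow(cases), chains = chains,
                   selected_features = sel,
                   eemd = cfg$eemd,
                   n_hc = cfg$cohort$n_hc, n_oa = cfg$cohort$n_oa,
                   package_version = as.character(utils::packageVersion("vagdx")))
  out <- structure(list(feature_table = cases, nca = nca,
                        selected_features = sel, split = split,
                        searches = searches, reports = reports,
                        manifest = manifest, X = Xcls, labels = labels),
                   class = "vag_run")
  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
    od <- cfg$output_dir
    write_feature_table(cases, file.path(od, "features.csv"))
    nca_weight_table(nca, file.path(od, "nca_weights.csv"))
    for (fam in names(searches))
      write.csv(searches[[fam]]$leaderboard,
                file.path(od, sprintf("leaderboard_%s.csv", fam)),
                row.names = FALSE, quote = FALSE)
    for (fam in names(reports))
      write_report(reports[[fam]], file.path(od, sprintf("report_%s.json", fam)))
    jsonlite::write_json(manifest, file.path(od, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}

#' @export
print.vag_run <- function(x, ...) {
  cat(sprintf("<vag_run> variant %s: %d cases, selected {%s}\n",
              x$manifest$variant, x$manifest$n_cases,
              paste(x$selected_features, collapse = ", ")))
  for (fam in names(x$reports))
    cat(sprintf("  %s (%s): test acc %.2f%%, AUC %.3f\n", fam,
                network_name(x$searches[[fam]]$best),
                x$reports[[fam]]$accuracy_pct, x$reports[[fam]]$auc))
  invisible(x)
}

# ---- command-line entry point -----------------------------------------------

.cli_usage <- function() {
  paste(
    "usage: vagdx <subcommand> [--config FILE] [--seed N] [--variant I|II|III]",
    "             [--out DIR] [--in FILE] [--verbose]",
    "subcommands:",
    "  simulate    generate a synthetic cohort and write recording CSVs",
    "  preprocess  clean one recording CSV (cycle cut + EEMD + detrend + [0,1])",
    "  features    extract the 12 signal measures from one recording CSV",
    "  select      NCA feature selection on a feature-table CSV",
    "  train       model search on a feature-table CSV",
    "  evaluate    train + test-set evaluation report from a feature-table CSV",
    "  run         full pipeline for one variant",
    sep = "\n")
}

# key = value pipeline config file (one pair per line, '#' comments)
.cli_read_config <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, ":", fixed = TRUE)
  vals <- lapply(kv, function(p) trimws(paste(p[-1], collapse = ":")))
  names(vals) <- vapply(kv, function(p) trimws(p[1]), "")
  vals
}

.cli_num <- function(vals, key, default) {
  if (!is.null(vals[[key]])) as.numeric(vals[[key]]) else default
}

#' Command-line entry point
#'
#' Thin argv-level interface over the package functions; see `--help` for the
#' subcommand list. Returns (rather than calls) the exit code: 0 on success,
#' 1 on runtime error, 2 on usage/config error.
#'
#' @param argv character vector of arguments (default: the R session's
#'   trailing command-line arguments).
#' @return integer exit code, invisibly.
#' @export
vag_cli <- function(argv = commandArgs(trailingOnly = TRUE)) {
  if (length(argv) == 0 || argv[1] %in% c("--help", "-h", "help")) {
    cat(.cli_usage(), "\n")
    return(invisible(0L))
  }
  sub <- argv[1]
  known <- c("simulate", "preprocess", "features", "select", "train",
             "evaluate", "run")
  if (!sub %in% known) {
    message("unknown subcommand: ", sub, "\n", .cli_usage())
    return(invisible(2L))
  }
  args <- argv[-1]
  opt <- list(seed = 1L, variant = "I", out = ".", input = NULL,
              config = NULL, verbose = FALSE)
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    take <- function() { i <<- i + 1; if (i > length(args)) stop("missing value for ", a); args[i] }
    res <- tryCatch({
      switch(a,
             "--config" = opt$config <- take(),
             "--seed" = opt$seed <- as.integer(take()),
             "--variant" = opt$variant <- take(),
             "--out" = opt$out <- take(),
             "--in" = opt$input <- take(),
             "--verbose" = opt$verbose <- TRUE,
             "--help" = { cat(.cli_usage(), "\n"); return(invisible(0L)) },
             stop("unknown flag: ", a))
      NULL
    }, error = function(e) e)
    if (inherits(res, "error")) {
      message(conditionMessage(res), "\n", .cli_usage())
      return(invisible(2L))
    }
    i <- i + 1
  }
  if (!opt$variant %in% c("I", "II", "III")) {
    message("invalid --variant: ", opt$variant)
    return(invisible(2L))
  }
  vals <- list()
  if (!is.null(opt$config)) {
    if (!file.exists(opt$config)) {
      message("config file not found: ", opt$config)
      return(invisible(2L))
    }
    vals <- .cli_read_config(opt$config)
  }
  log <- function(...) if (opt$verbose) message(...)
  build_cfg <- function() {
    cohort <- vag_config(
      n_hc = .cli_num(vals, "n_hc", 33L), n_oa = .cli_num(vals, "n_oa", 34L),
      seed = opt$seed, n_cycles = .cli_num(vals, "n_cycles", 10L),
      knees_per_hc = .cli_num(vals, "knees_per_hc", 2L))
    pipeline_config(variant = opt$variant, cohort = cohort,
                    eemd = list(noise_std = .cli_num(vals, "noise_std", 0.2),
                                n_trials = as.integer(.cli_num(vals, "n_trials", 100))),
                    output_dir = opt$out, seed = opt$seed)
  }
  code <- tryCatch({
    switch(sub,
      simulate = {
        cfg <- build_cfg()
        cohort <- generate_cohort(cfg$cohort)
        dir.create(opt$out, recursive = TRUE, showWarnings = FALSE)
        for (i in seq_along(cohort$recordings)) {
          rec <- cohort$recordings[[i]]
          write_recording(rec, file.path(opt$out,
            sprintf("%s_%s_k%d.csv", rec$subject$subject_id, rec$chain, rec$knee)))
        }
        write.csv(cohort$manifest, file.path(opt$out, "cohort_manifest.csv"),
                  row.names = FALSE, quote = FALSE)
        log("wrote ", length(cohort$recordings), " recordings to ", opt$out)
      },
      preprocess = , features = {
        if (is.null(opt$input)) stop("--in FILE required")
        rec <- read_recording(opt$input)
        cfg <- build_cfg()
        pp <- preprocess_recording(rec, noise_std = cfg$eemd$noise_std,
                                   n_trials = cfg$eemd$n_trials, seed = opt$seed)
        if (sub == "preprocess") {
          dir.create(opt$out, recursive = TRUE, showWarnings = FALSE)
          writeLines(format(pp$signal, digits = 15, trim = TRUE),
                     file.path(opt$out, "cleaned_signal.txt"))
        } else {
          f <- extract_features(unlist(pp$cycles, use.names = FALSE))
          cat(paste(names(f), format(f, digits = 10), sep = ","), sep = "\n")
        }
      },
      select = {
        if (is.null(opt$input)) stop("--in FILE required")
        tab <- read_feature_table(opt$input)
        nca <- fit_nca(as.matrix(tab[, vag_feature_names()]), tab$label,
                       seed = opt$seed)
        dir.create(opt$out, recursive = TRUE, showWarnings = FALSE)
        nca_weight_table(nca, file.path(opt$out, "nca_weights.csv"))
      },
      train = , evaluate = {
        if (is.null(opt$input)) stop("--in FILE required")
        tab <- read_feature_table(opt$input)
        X <- as.matrix(cbind(tab[, vag_feature_names()],
                             age = tab$age, sex = as.numeric(tab$sex),
                             bmi = tab$bmi))
        split <- split_dataset(tab$label, seed = opt$seed)
        dir.create(opt$out, recursive = TRUE, showWarnings = FALSE)
        for (fam in c("MLP", "RBF")) {
          s <- model_search(X, tab$label, split, fam, seed = opt$seed)
          write.csv(s$leaderboard,
                    file.path(opt$out, sprintf("leaderboard_%s.csv", fam)),
                    row.names = FALSE, quote = FALSE)
          if (sub == "evaluate") {
            P <- predict_proba(s$best, X[split$test, , drop = FALSE])
            rep <- evaluation_report(tab$label[split$test], P[, "OA"])
            write_report(rep, file.path(opt$out, sprintf("report_%s.json", fam)))
          }
        }
      },
      run = {
        cfg <- build_cfg()
        res <- run_variant(cfg)
        log("variant ", cfg$variant, " done: ",
            paste(names(res$reports), vapply(res$reports, function(r)
              sprintf("%.1f%%", r$accuracy_pct), ""), collapse = ", "))
      })
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(code)
}
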