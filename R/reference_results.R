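#' Reference confusion counts of the patellofemoral VAG study
#'
#' Per-class case and correct-classification counts published for the six
#' best networks of the reference clinical study of patellofemoral-joint
#' vibroarthrography (two network families by three kinetic-chain variants;
#' variant I = open chain, II = closed chain, III = both chains stacked).
#' These printed counts are the worked-example inputs against which the
#' [confusion_metrics()] implementation can be checked end to end: every
#' derived percentage, F1 and MCC in the study's summary tables follows from
#' them.
#'
#' @return data.frame with one row per network: `network`, `variant`,
#'   `family`, `hc_total`, `hc_correct`, `oa_total`, `oa_correct`.
#' @export
reference_confusion_counts <- function() {
  data.frame(
    network = c("MLP 9-40-2", "RBF 9-35-2", "MLP 10-16-2",
                "RBF 10-40-2", "MLP 8-3-2", "RBF 8-14-2"),
    variant = c("I", "I", "II", "II", "III", "III"),
    family = c("MLP", "RBF", "MLP", "RBF", "MLP", "RBF"),
    hc_total = c(45, 45, 45, 45, 89, 89),
    hc_correct = c(43, 44, 44, 43, 88, 85),
    oa_total = c(23, 23, 23, 23, 47, 47),
    oa_correct = c(18, 23, 23, 23, 45, 40),
    stringsAsFactors = FALSE
  )
}

#' Metrics recomputed from the reference confusion counts
#'
#' Applies [confusion_metrics()] to every row of
#' [reference_confusion_counts()]: `tp = oa_correct`,
#' `fn = oa_total - oa_correct`, `tn = hc_correct`,
#' `fp = hc_total - hc_correct`.
#'
#' @return data.frame with the network identifiers and the derived
#'   per-class percentages, accuracy, sensitivity, specificity, precision,
#'   F1 and MCC.
#' @export
reference_metrics <- function() {
  ref <- reference_confusion_counts()
  rows <- lapply(seq_len(nrow(ref)), function(i) {
    m <- confusion_metrics(confusion_counts(
      tp = ref$oa_correct[i], fn = ref$oa_total[i] - ref$oa_correct[i],
      tn = ref$hc_correct[i], fp = ref$hc_total[i] - ref$hc_correct[i]))
    data.frame(network = ref$network[i], variant = ref$variant[i],
               family = ref$family[i],
               hc_correct_pct = m$hc_correct_pct,
               oa_correct_pct = m$oa_correct_pct,
               accuracy_pct = m$accuracy_pct,
               sensitivity = m$sensitivity, specificity = m$specificity,
               precision = m$precision, f1 = m$f1, mcc = m$mcc)
  })
  do.call(rbind, rows)
}
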