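#' Published reference classification results
#'
#' The mean confusion-matrix cells (TP/FN/FP/TN, summed over the 5 folds of
#' a repeat and averaged over 20 repeats) and derived rates reported by the
#' clinical smoker / non-smoker FLIO study whose design this package
#' emulates, for both tasks (all smokers vs non-smokers, 56 + 52 eyes; heavy
#' smokers vs non-smokers, 28 + 52 eyes) and all ten feature subsets. The
#' `prose_*` columns carry the whole-percent values quoted in that study's
#' running text. Used as worked-example inputs: [confusion_metrics()] on the
#' cells must reproduce the printed rates.
#'
#' @return Data frame with one row per (task, feature subset).
#' @export
reference_results <- function() {
  read.csv(system.file("extdata", "reference_svm_results.csv",
                       package = "fliopipe", mustWork = TRUE),
           stringsAsFactors = FALSE)
}
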