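# RBF-kernel SVM classification under grouped stratified repeated 5-fold
# cross-validation, with confusion-matrix aggregation matching the published
# result-table convention: cells are summed over the k folds within a repeat
# (every sample predicted exactly once per repeat) and then averaged over
# repeats.

#' SVM configuration
#'
#' @param C Soft-margin penalty (> 0, default 1).
#' @param gamma RBF kernel width: `"scale"` (default; `1 / (d * var(X))`
#'   with `var(X)` the variance of the standardized training matrix's
#'   entries) or an explicit positive value.
#' @param standardize Z-score each feature on the training rows before
#'   fitting (default `TRUE`; lifetimes in ps and intensities in counts are
#'   not comparable without it).
#' @return An `svm_config`.
#' @export
svm_config <- function(C = 1, gamma = "scale", standardize = TRUE) {
  stopifnot(C > 0, identical(gamma, "scale") || (is.numeric(gamma) && gamma > 0))
  structure(list(C = C, gamma = gamma, standardize = standardize),
            class = "svm_config")
}

#' Cross-validation configuration
#'
#' @param k Number of folds (default 5).
#' @param repeats Number of repeated CV iterations (default 20).
#' @param positive_class `"smoker"` (light + heavy vs non) or
#'   `"heavy_smoker"` (heavy vs non; light smokers dropped).
#' @param seed Base seed; each repeat derives its own shuffling seed.
#' @param paper_mode_selection For the `ttest_top3` subset: select the three
#'   features once on the full dataset (the published protocol) instead of
#'   re-ranking inside each training fold (leakage-safe default).
#' @return A `cv_config`.
#' @export
cv_config <- function(k = 5, repeats = 20,
                      positive_class = c("smoker", "heavy_smoker"),
                      seed = 1L, paper_mode_selection = FALSE) {
  stopifnot(k >= 2, repeats >= 1)
  structure(list(k = k, repeats = repeats,
                 positive_class = match.arg(positive_class),
                 seed = as.integer(seed),
                 paper_mode_selection = paper_mode_selection),
            class = "cv_config")
}

#' Grouped stratified fold assignment
#'
#' Within each stratum (subject-level smoking status), subjects are shuffled
#' with a per-repeat seed and dealt round-robin into the k folds starting at
#' fold 1, so stratum fold sizes differ by at most 1 and every eye of a
#' subject follows its subject. With strata of 26/14/14 subjects and k = 5
#' this yields fold subject counts {12, 11, 11, 11, 9}.
#'
#' @param subjects Data frame with columns `subject_id` and `stratum`.
#' @param cv A [cv_config()].
#' @param repeat_index Which repeat (1-based) the folds are for.
#' @return List of k character vectors of subject ids.
#' @export
make_folds <- function(subjects, cv = cv_config(), repeat_index = 1) {
  stopifnot(nrow(subjects) > 0, all(c("subject_id", "stratum") %in% names(subjects)))
  folds <- rep(list(character()), cv$k)
  strata <- split(subjects$subject_id,
                  factor(subjects$stratum, levels = unique(subjects$stratum)))
  for (si in seq_along(strata)) {
    ids <- strata[[si]]
    shuffled <- withr::with_seed(
      derive_seed(cv$seed, repeat_index, names(strata)[si], "folds"),
      sample(ids))
    assign_to <- rep_len(seq_len(cv$k), length(shuffled))
    for (f in seq_len(cv$k))
      folds[[f]] <- c(folds[[f]], shuffled[assign_to == f])
  }
  folds
}

#' Confusion-matrix rates
#'
#' @param tp,fn,fp,tn Confusion cells (reals >= 0; repeat means are
#'   fractional).
#' @return Named vector `c(tpr, fpr, accuracy)` in percent. Zero
#'   denominators give `NA` with a warning rather than a silent value.
#' @export
confusion_metrics <- function(tp, fn, fp, tn) {
  pos <- tp + fn; neg <- fp + tn
  if (pos == 0 || neg == 0) {
    warning("confusion_metrics: zero positives or negatives; rates undefined")
    return(c(tpr = if (pos == 0) NA_real_ else unname(tp / pos * 100),
             fpr = if (neg == 0) NA_real_ else unname(fp / neg * 100),
             accuracy = unname((tp + tn) / (pos + neg) * 100)))
  }
  c(tpr = unname(tp / pos * 100), fpr = unname(fp / neg * 100),
    accuracy = unname((tp + tn) / (pos + neg) * 100))
}

#' Train an RBF-kernel SVM
#'
#' Fits the feature scaler (training-fold means/SDs; missing values imputed
#' by training-fold feature means) and a soft-margin RBF SVM.
#'
#' @param train_features Numeric matrix or data frame of training rows.
#' @param train_labels Two-level label vector.
#' @param config An [svm_config()].
#' @return A `flio_svm` classifier; use [predict()] with new feature rows.
#' @export
train_svm <- function(train_features, train_labels, config = svm_config()) {
  X <- as.matrix(train_features)
  y <- factor(train_labels)
  if (nlevels(y) < 2) stop("train_svm: training set contains a single class")
  col_mean <- apply(X, 2, function(v) {
    m <- mean(v, na.rm = TRUE); if (is.nan(m)) 0 else m
  })
  for (j in seq_len(ncol(X))) X[is.na(X[, j]), j] <- col_mean[j]
  if (config$standardize) {
    ctr <- colMeans(X)
    scl <- apply(X, 2, sd); scl[scl == 0] <- 1
  } else {
    ctr <- rep(0, ncol(X)); scl <- rep(1, ncol(X))
  }
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  gamma <- if (identical(config$gamma, "scale")) {
    v <- mean((Xs - mean(Xs))^2)
    if (v > 0) 1 / (ncol(Xs) * v) else 1 / ncol(Xs)
  } else config$gamma
  fit <- e1071::svm(x = Xs, y = y, kernel = "radial", cost = config$C,
                    gamma = gamma, scale = FALSE)
  structure(list(fit = fit, impute = col_mean, center = ctr, scale = scl,
                 gamma = gamma, features = colnames(X), config = config),
            class = "flio_svm")
}

#' @export
predict.flio_svm <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (!is.null(object$features) && !is.null(colnames(X)))
    X <- X[, object$features, drop = FALSE]
  for (j in seq_len(ncol(X))) X[is.na(X[, j]), j] <- object$impute[j]
  Xs <- sweep(sweep(X, 2, object$center), 2, object$scale, "/")
  predict(object$fit, Xs)
}

# Map 3-level smoking labels to the binary task, dropping light smokers for
# the heavy experiment. Returns the filtered table plus positive label name.
binarize_task <- function(table, positive_class) {
  if (positive_class == "heavy_smoker") {
    table <- table[table$label != "light_smoker", , drop = FALSE]
    positive <- table$label == "heavy_smoker"
  } else {
    positive <- table$label %in% c("light_smoker", "heavy_smoker")
  }
  list(table = table, positive = positive)
}

#' Repeated grouped stratified cross-validation of the SVM
#'
#' For each repeat, subjects are dealt into k folds ([make_folds()],
#' stratified by smoking status), the SVM is trained on k - 1 folds and
#' predicts the held-out eyes, and TP/FN/FP/TN are summed over the k folds
#' (so every sample is predicted exactly once per repeat). Cell means, rates
#' and rate SDs are then taken over the repeats ([cv_result()]).
#'
#' For `subset = "ttest_top3"` the three most significant lifetime features
#' are re-ranked inside each training fold by default (leakage-safe);
#' `cv$paper_mode_selection = TRUE` selects them once on the full dataset,
#' the published protocol.
#'
#' @param table A [feature_table()] labelled with smoking status.
#' @param subset Feature subset name ([flio_subset_names()]) or a character
#'   vector of feature columns.
#' @param cv A [cv_config()].
#' @param svm An [svm_config()].
#' @return A [cv_result()].
#' @export
run_cv <- function(table, subset = "all", cv = cv_config(), svm = svm_config()) {
  stopifnot(inherits(table, "feature_table"), nrow(table) > 0)
  task <- binarize_task(table, cv$positive_class)
  tab <- task$table
  y <- factor(ifelse(task$positive, "positive", "negative"),
              levels = c("negative", "positive"))
  fold_selection <- identical(subset, "ttest_top3") && !cv$paper_mode_selection
  if (!fold_selection) {
    tab_sel <- select_subset(tab, subset, labels = y)
    cols <- feature_names(tab_sel)
  }
  subjects <- unique(data.frame(subject_id = tab$subject_id,
                                stratum = tab$label, stringsAsFactors = FALSE))
  per_repeat <- vector("list", cv$repeats)
  for (r in seq_len(cv$repeats)) {
    folds <- make_folds(subjects, cv, r)
    cells <- c(tp = 0L, fn = 0L, fp = 0L, tn = 0L)
    for (f in seq_len(cv$k)) {
      test_idx <- tab$subject_id %in% folds[[f]]
      if (!any(test_idx)) next
      if (fold_selection) {
        ranking <- ttest_rank(tab[!test_idx, ], y[!test_idx],
                              features = flio_subset_columns("tau_m"))
        cols <- ranking$feature[1:3]
      }
      X <- as.matrix(as.data.frame(tab)[, cols, drop = FALSE])
      model <- train_svm(X[!test_idx, , drop = FALSE], y[!test_idx], svm)
      pred <- predict(model, X[test_idx, , drop = FALSE])
      truth <- y[test_idx]
      cells <- cells + c(
        tp = sum(pred == "positive" & truth == "positive"),
        fn = sum(pred == "negative" & truth == "positive"),
        fp = sum(pred == "positive" & truth == "negative"),
        tn = sum(pred == "negative" & truth == "negative"))
    }
    per_repeat[[r]] <- cells
  }
  cv_result(per_repeat, config = list(
    subset = if (is.character(subset) && length(subset) == 1) subset else "custom",
    features = if (fold_selection) "ttest_top3 (per-fold selection)" else cols,
    k = cv$k, repeats = cv$repeats, seed = cv$seed,
    positive_class = cv$positive_class,
    paper_mode_selection = cv$paper_mode_selection,
    C = svm$C, gamma = svm$gamma, standardize = svm$standardize))
}
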